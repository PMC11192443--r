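a
an
the
and
or
but
nor
so
yet
of
in
on
at
to
into
onto
from
by
with
for
as
about
after
before
between
through
during
over
under
up
down
out
off
again
then
than
there
here
is
are
was
were
be
been
being
am
do
does
did
doing
have
has
had
having
will
would
can
could
should
shall
may
might
must
i
me
my
mine
you
your
yours
he
him
his
she
her
hers
it
its
we
us
our
ours
they
them
their
theirs
this
that
these
those
who
whom
whose
which
what
when
where
why
how
all
each
both
few
more
most
other
some
any
no
not
only
own
same
such
too
very
just
also
s
t
ll
re
ve
d
m
o
don
now
while
if
because
until
once
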