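{
  "toy": {
    "1": {
      "a": "I think the dog chased the ball. The dog jumped.",
      "b": "A dog was chasing a ball in this clip.",
      "c": "Maybe the dogs ran after the ball."
    },
    "2": {
      "a": "The dog sat. It seems like the cat was eating.",
      "b": "Dogs eat. The cat sat there.",
      "c": "A cat ate. Probably the dog was sitting."
    }
  }
}
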