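same as before
as before
in this clip
in the clip
in this scene
in the scene
in this video
in the video
this clip
the clip
the camera
the screen
the scene
the video
the audio
the recording
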