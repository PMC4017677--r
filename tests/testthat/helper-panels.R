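# Panel fixture shared with the package: tests refer to it under the
# historical helper name.
make_screen_panel <- function() screen_panel()
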