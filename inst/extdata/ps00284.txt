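ID   SERPIN; PATTERN.
AC   PS00284;
DE   Serpins signature.
PA   [LIVMFY]-x-[LIVMFYAC]-[DNQ]-[RKHQS]-[PST]-F-[LIVMFY]-[LIVMFYC]-x-
PA   [LIVMFAH].
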