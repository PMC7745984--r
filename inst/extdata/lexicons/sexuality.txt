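# Sexuality labels.
heterosexual heterosexual Heterosexual
homosexual homosexual Homosexual
queer queer Queer
gay gay Gay
lesbian lesbian Lesbian
bisexual bisexual Bisexual
straight straight Straight
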