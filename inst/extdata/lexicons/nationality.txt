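# Nationality / ethnicity labels.
british british British
irish irish Irish
african_american african_american African_american African_American
american american American
chinese chinese Chinese
italian italian Italian
polish polish Polish
german german German
english english English
asian asian Asian
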