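# Religion labels.
christian christian Christian
atheist atheist Atheist
muslim muslim Muslim
jew jew Jew
jewish jewish Jewish
sikh sikh Sikh
hindu hindu Hindu
buddhist buddhist Buddhist
catholic catholic Catholic
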