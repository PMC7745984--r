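# Pole words for semantic-axis placements.
safe safe Safe
dangerous dangerous Dangerous
violent violent Violent
innocent innocent Innocent
suicide suicide Suicide
healthy healthy Healthy
he he He
she she She
heterosexual heterosexual Heterosexual
homosexual homosexual Homosexual
cis_gender cis_gender Cis_gender
trans_gender trans_gender Trans_gender
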