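# Gender labels (UK/USA census-style), one entry per line:
# canonical followed by case variants as found in mixed-case vocabularies.
queer queer Queer
gender_fluid gender_fluid Gender_fluid
man man Man
cis_gender cis_gender Cis_gender
trans_gender trans_gender Trans_gender
woman woman Woman
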