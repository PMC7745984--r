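# Gendered family terms used for pole-axis placements.
mother mother Mother
father father Father
mum mum Mum
dad dad Dad
aunt aunt Aunt
uncle uncle Uncle
sister sister Sister
brother brother Brother
daughter daughter Daughter
son son Son
grandmother grandmother Grandmother
grandfather grandfather Grandfather
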