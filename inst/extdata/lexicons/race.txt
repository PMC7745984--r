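# Racial demographic labels (UK/USA census-style).
latino latino Latino
african_american african_american African_american African_American
native_american native_american Native_american Native_American
asian_american asian_american Asian_american Asian_American
asian asian Asian
hispanic hispanic Hispanic
white white White
black black Black
latinx latinx Latinx
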