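# Age-group labels.
grandparent grandparent Grandparent
parent parent Parent
adolescent adolescent Adolescent
teenager teenager Teenager
child child Child
youth youth Youth
elderly elderly Elderly
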