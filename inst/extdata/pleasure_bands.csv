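scheme,style,band
painting,Romanticism,Pleased
painting,Impressionistic,Pleased
painting,Post-impressionistic,Pleased
painting,Renaissance,General
painting,Baroque,General
painting,Modernism,General
painting,Abstractionism,General
painting,Contemporary art,Unpleased
interior,Nordic,Pleased
interior,American,Pleased
interior,French,General
interior,Modern,General
interior,New Chinese,General
interior,Pastoralism,Unpleased
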