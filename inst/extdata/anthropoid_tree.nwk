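# Synthetic consensus-style chronogram of 16 anthropoid terminal taxa
# (hominoids to species, monkeys to genus, hylobatids pooled). Node ages in
# Myr are fixture constants rounded from literature-standard divergence dates,
# not scientific claims: root (platyrrhine-catarrhine) 40, crown platyrrhines
# 24, Ateles-Alouatta 16, crown catarrhines 30, crown cercopithecids 18,
# Macaca split 12, Mandrillus split 8, Papio-Theropithecus 5, crown hominoids
# 18, crown hominids 16, crown Pongo 3, crown hominines 9, crown Gorilla 2,
# Pan-Homo 7, Pan species 2.5. Fossil tips (4.4, 2, 18, 9.6 Myr + 1-Myr ghost
# lineages) are grafted in code by packaged_anthropoid_tree(fossils = TRUE).
((Cebus:24,(Ateles:16,Alouatta:16):8):16,((Nasalis:18,(Macaca:12,(Mandrillus:8,(Papio:5,Theropithecus:5):3):4):6):12,(Hylobatidae:18,((Pongo_abelii:3,Pongo_pygmaeus:3):13,((Gorilla_gorilla:2,Gorilla_beringei:2):7,(Homo_sapiens:7,(Pan_troglodytes:2.5,Pan_paniscus:2.5):4.5):2):7):2):12):10);
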