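# First backcross of the combined large-grain/semidwarf scheme:
# Koshihikari x (GW2 d60 Gal homozygous donor segregant), F1 selfed.
loci:
  - name: GW2
    alleles: [GW2, gw2]     # donor allele first (Inochinoichi large-grain)
    chromosome: chr2
    pos_mb: 8.1
  - name: D60
    alleles: [d60, D60]     # donor allele is the semidwarfing d60
    chromosome: chr2
  - name: Gal
    alleles: [Gal, gal]
groups:
  chr2: [GW2, D60]
  gal: [Gal]
r:
  chr2: [0.176]
  gal: []
lethal:
  sex: both
  combos:
    - {D60: d60, Gal: gal}
founders:
  Koshihikari:
    hap1: {GW2: gw2, D60: D60, Gal: gal}
    hap2: {GW2: gw2, D60: D60, Gal: gal}
  donor:
    hap1: {GW2: GW2, D60: d60, Gal: Gal}
    hap2: {GW2: GW2, D60: d60, Gal: Gal}
steps:
  - {name: BC1F1, op: cross, female: Koshihikari, male: donor, size: 1}
  - {name: BC1F2, op: self, parent: BC1F1, size: 112}
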