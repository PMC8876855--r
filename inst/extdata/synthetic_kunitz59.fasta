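>synthetic_kunitz59 SYNTHETIC stand-in: 59-residue Kunitz-like scaffold (6 Cys, 3 disulfide bridges); not a natural sequence
INGKCSLPAEVGPCRARFPSYYYNSESNKCEKFTYGGCGGNANNFETRDECRETCGGKA
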