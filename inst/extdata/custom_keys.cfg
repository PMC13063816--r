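# Default fingerprint customization: 43 replacements (26% of the 166-key
# dictionary).  Inorganic-, metal- and halogen-related standard keys that
# carry no signal for CHONS organics are replaced by substructure families
# associated with organic cytotoxicity (reactive carbonyls, aromatic
# nitrogen chemistry, heterocycles, alkyl/unsaturation descriptors).
# Every definition here is this package's own reconstruction of such a
# customization; patterns are editable.
#
# Format: one [bit N] block per entry with keys
#   smarts      = substructure query (SMARTS)
#   min_count   = bit fires when unique matches >= min_count (default 1)
#   description = human-readable substructure name
#   action      = replace | remove   (default replace)

[bit 0]
smarts = c[NX3;H2]
description = primary aromatic amine (aniline-type)

[bit 2]
smarts = c[NX3;H1][#6]
description = secondary aromatic amine

[bit 4]
smarts = c[NX3]([#6])[#6]
description = N,N-disubstituted aromatic amine

[bit 6]
smarts = cC(=[OX1])[#6]
description = aromatic alpha,beta-unsaturated ketone (aryl ketone)

[bit 8]
smarts = cC(=[OX1])c
description = diaryl ketone

[bit 10]
smarts = c[CX3H1]=[OX1]
description = aromatic aldehyde

[bit 12]
smarts = [OX1]=[#6]1[#6]=,:[#6][#6](=[OX1])[#6]=,:[#6]1
description = quinone (cyclic conjugated diketone)

[bit 14]
smarts = [OX1]=[CX3][CX3]=[OX1]
description = 1,2-dicarbonyl (alpha-oxo ketone)

[bit 16]
smarts = c[CX3](=[OX1])[OX2][#6]
description = aromatic carboxylic ester

[bit 18]
smarts = c[CX3](=[OX1])[OX2H]
description = aromatic carboxylic acid

[bit 20]
smarts = c[CX3](=[OX1])[NX3]
description = aromatic amide (benzamide-type)

[bit 22]
smarts = [NX3][CX3](=[OX1])[CX4]
description = aliphatic amide

[bit 24]
smarts = [nX2]1ccccc1
description = pyridine ring

[bit 26]
smarts = [nX3H1]1cccc1
description = pyrrole-type NH five-ring

[bit 28]
smarts = o1cccc1
description = furan ring

[bit 30]
smarts = s1cccc1
description = thiophene ring

[bit 32]
smarts = [n]1ccc2ccccc12
description = fused bicyclic N-heteroaromatic (indole-like)

[bit 34]
smarts = [#7;R;!a]
description = non-aromatic N-heterocycle nitrogen

[bit 36]
smarts = [#8;R;!a]
description = non-aromatic O-heterocycle oxygen

[bit 38]
smarts = [n][n]
description = adjacent aromatic nitrogens (pyrazole/pyridazine-like)

[bit 40]
smarts = c[NX2]=[NX2]c
description = aromatic azo group

[bit 42]
smarts = [NX2]=[OX1]
description = nitroso group

[bit 44]
smarts = [$([NX4+][OX1-]),$([nX3+][OX1-])]
description = amine or pyridine N-oxide

[bit 46]
smarts = c[$([NX3](=O)=O),$([NX3+](=O)[O-])]
description = aromatic nitro group

[bit 48]
smarts = [CX4][$([NX3](=O)=O),$([NX3+](=O)[O-])]
description = aliphatic nitro group

[bit 50]
smarts = c[CX2]#[NX1]
description = aromatic nitrile

[bit 52]
smarts = [OX2H]c1ccccc1[OX2H]
description = catechol (1,2-dihydroxybenzene)

[bit 58]
smarts = [OX2H]c1ccc(cc1)[OX2H]
description = hydroquinone (1,4-dihydroxybenzene)

[bit 61]
smarts = c1ccc2ccccc2c1
description = naphthalene core (two fused benzene rings)

[bit 67]
smarts = [aR2]
min_count = 4
description = polycyclic aromatic system (three or more fused rings)

[bit 70]
smarts = c[OX2][CH3]
description = aryl methyl ether (anisole-type)

[bit 73]
smarts = [CX3]=[CX3][CX3]=[OX1]
description = alpha,beta-unsaturated carbonyl (Michael acceptor)

[bit 79]
smarts = [CX3]=[CX3][CX3](=[OX1])[OX2]
description = alpha,beta-unsaturated ester (acrylate-type)

[bit 85]
smarts = [OX2H][CX4][CX4][NX3]
description = N-(2-hydroxyethyl)amine (ethanolamine motif)

[bit 91]
smarts = [NX3]([CX4])([CX4])[CX4]
min_count = 2
description = two or more trialkylamine nitrogens

[bit 97]
smarts = [CX4H2][CX4H2][CX4H2][CX4H2][CX4H2][CX4H2]
description = long alkyl chain (six or more consecutive methylenes)

[bit 103]
smarts = [CX4H2][CX4H2][CX4H2][CX4H2]
description = alkyl chain (four or more consecutive methylenes)

[bit 109]
smarts = [CX4]([CH3])([CH3])[CH3]
description = tert-butyl branch

[bit 115]
smarts = [CX2]#[CX2]
description = internal or terminal triple bond

[bit 121]
smarts = c[SX2][#6]
description = aryl thioether

[bit 127]
smarts = c[SX4](=[OX1])=[OX1]
description = aryl sulfonyl group

[bit 129]
smarts = c[CX3](=[OX1])[CX3]=[CX3]
description = aryl vinyl ketone (aromatic Michael acceptor)

[bit 165]
smarts = [NX3]([CX4])([CX4])[CX4]
description = tertiary aliphatic amine
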