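# Shared benchmark structures (also available via fixture_corpus()).
FIG1 <- "C1CC2CCC1CCC3CCC(CC3)CC2"        # three-class bicyclic cage
FIG2 <- "C12C3C1C4C5C4C5C23"              # all-3-ring polycycle
OXIRANE <- "CC1CO1"                        # 2-methyloxirane
FIG7 <- "C[C@H]1CC[C@H](N)CC1"            # relative stereo, no chiral centres
FULLERENE24 <- "C1(C2C3C4C15)C6C7C2C8C3C9C%10C4C%11C5C6C%12C%11C%10C%13C%12C7C8C9%13"
ADAMANTANE <- "C1C2CC3CC1CC(C2)C3"
CUBANE <- "C12C3C4C1C5C2C3C45"
PETERSEN72 <- "C12C3C4C5C1C6C7C2C8C3C6C5C8C74"
POLYETHER_CAGE <- "C1OC23COC45COC11COC67COC8(COC9(CO2)COC(CO1)(CO6)OCC(CO9)(OC4)OCC(CO5)(OC7)OC8)OC3"

parse_norm <- function(s) normalize_molecule(parse_smiles(s))

# n random relabelings of a molecule as SMILES strings
relabelings <- function(mol, n) {
  vapply(seq_len(n), function(i) random_smiles(mol), character(1))
}
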