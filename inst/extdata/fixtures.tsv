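name	smiles	expected_classes	expected_traversals	provenance
bicyclic_cage	C1CC2CCC1CCC3CCC(CC3)CC2	3	16	three-class cage that local invariants alone merge into two classes
tricyclic_octane	C12C3C1C4C5C4C5C23	NA	16	all-3-ring polycycle distinguishing the per-bond ring-size products
methyloxirane	CC1CO1	4	1	epoxide whose one-pass squared-prime scores are worked by hand
dimethyl_cyclohexane_diamine_skeleton	C[C@H]1CC[C@H](N)CC1	NA	2	trans-4-methylcyclohexan-1-amine-type relative stereochemistry, no chiral centres
fullerene24	C1(C2C3C4C15)C6C7C2C8C3C9C%10C4C%11C5C6C%12C%11C%10C%13C%12C7C8C9%13	2	NA	24-vertex fullerene separated only by the distance-shell invariant
adamantane	C1C2CC3CC1CC(C2)C3	2	24	adamantane, |Aut| = 24
cubane	C12C3C4C1C5C2C3C45	1	48	cubane, |Aut| = 48
petersen_7_2	C12C3C4C5C1C6C7C2C8C3C6C5C8C74	1	28	generalized Petersen graph G(7,2); known false merge to one class
polyether_cage	C1OC23COC45COC11COC67COC8(COC9(CO2)COC(CO1)(CO6)OCC(CO9)(OC4)OCC(CO5)(OC7)OC8)OC3	3	NA	polyether cage with trivial automorphism group; known false merge to three classes
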