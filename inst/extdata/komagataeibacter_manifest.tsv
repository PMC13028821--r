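accession	species	strain	size_bp	source	excluded_clonal
GCF_000182745.2	Komagataeibacter medellinensis	NBRC 3288	3513191	Vinegar	FALSE
GCF_002009295.1	Komagataeibacter nataicola	RZS01	3760301	Rotten apple	FALSE
GCF_002173515.1	Komagataeibacter europaeus	SRCM101446	3797909	NA	FALSE
GCF_003546645.1	Komagataeibacter saccharivorans	CV1	3768311	Vinegar	FALSE
GCF_004006375.1	Komagataeibacter xylinus	DSM 2325	3727795	NA	FALSE
GCF_004348195.1	Komagataeibacter saccharivorans	JH1	3727857	Fruit fly	FALSE
GCF_009834365.1	Komagataeibacter xylinus	CGMCC 17276	3983026	Green jujube	FALSE
GCF_019052775.1	Komagataeibacter oboediens	SI3053	3666777	Apple cider vinegar production	FALSE
GCF_029229465.1	Komagataeibacter oboediens	NCIB 8034	4059958	Kombucha tea culture	FALSE
GCF_029229505.1	Komagataeibacter nataicola	DS12	3916688	Kombucha tea culture	FALSE
GCF_032075085.1	Komagataeibacter nataicola	FWP-2023	3767936	NA	FALSE
GCF_034063025.1	Komagataeibacter rhaeticus	CGMCC 2955	3563316	Vinegar	FALSE
GCF_040581405.1	Komagataeibacter sucrofermentans	JCM 9730	3437745	Black cherry	FALSE
GCF_043995075.1	Komagataeibacter diospyri	MI2	3885945	Ripen Sapodilla fruit	FALSE
GCF_047795655.1	Komagataeibacter sucrofermentans	SMEG01	3442337	Apple	FALSE
GCF_049202445.1	Komagataeibacter intermedius	SLAM-NK6B	3661158	Kombucha	FALSE
GCF_052445895.1	Komagataeibacter intermedius	FM883	4235196	Kombucha tea	FALSE
GCF_900086575.1	Komagataeibacter rhaeticus	iGEM	3867346	Kombucha tea Scoby	FALSE
GCF_011611525.1	Komagataeibacter rhaeticus	ENS 9a1a	NA	NA	TRUE
GCF_014725815.1	Komagataeibacter rhaeticus	ENS9b	NA	NA	TRUE
GCF_040581375.1	Komagataeibacter sucrofermentans	JML KO23	NA	NA	TRUE
GCF_040581385.1	Komagataeibacter sucrofermentans	JML 2321	NA	NA	TRUE
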