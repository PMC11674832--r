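gene_id	hemizygous_phenotype	relative_fitness	overall_phenotype
CG11985	lethal		mutant
CG12384	lethal		mutant
CG13018	lethal		mutant
CG14036	low viability	lower fitness	mutant
CG17059	low viability		mutant
CG17278	low viability, leg phenotype		mutant
CG17343	lethal		mutant
CG17931	low viability		mutant
CG30415	lethal		mutant
CG33713	low viability		mutant
CG33714	semi-lethal		mutant
CG34250	viable	lower fitness	mutant
CG42497	lethal		mutant
CG44242	semi-lethal		mutant
CG6610	lethal		mutant
CG7630	viable	lower fitness	mutant
CG7646	viable, 50% heldout wings	equilibrated	mutant
CG8498	low viability		mutant
CG8788	viable	lower fitness	mutant
CG9034	lethal		mutant
l(2)06225	lethal		mutant
CG10418	viable	higher fitness	wild_type
CG12643	viable		wild_type
CG12994	viable		wild_type
CG13751	viable		wild_type
CG14104	viable	higher fitness	wild_type
CG15386	viable		wild_type
CG17127	viable		wild_type
CG17776	viable		wild_type
CG18081	viable	higher fitness	wild_type
CG18622	viable		wild_type
CG32267	viable	higher fitness	wild_type
CG32276	viable	higher fitness	wild_type
CG32368	viable		wild_type
CG33169	viable	higher fitness	wild_type
CG33170	viable	higher fitness	wild_type
CG3321	viable	higher fitness	wild_type
CG33672	viable	equilibrated	wild_type
CG34200	viable		wild_type
CG34242	viable	higher fitness	wild_type
CG42371	viable		wild_type
CG42394	viable	higher fitness	wild_type
CG5446	viable		wild_type
CG6615	viable		wild_type
CG6770	viable	higher fitness	wild_type
CG8860	viable		wild_type
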