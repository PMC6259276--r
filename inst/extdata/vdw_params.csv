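# Van der Waals parameters by element: radius R (Angstrom) and well depth
# epsilon (kcal/mol), Tripos 5.2 values (Clark, Cramer & Van Opdenbosch,
# J. Comput. Chem. 10 (1989) 982-1012, Table I). Pair parameters combine as
# R*_ij = R_i + R_j, eps_ij = sqrt(eps_i * eps_j).
element,radius,epsilon
H,1.50,0.042
C,1.70,0.107
N,1.55,0.095
O,1.52,0.116
S,1.80,0.314
Br,1.85,0.434
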