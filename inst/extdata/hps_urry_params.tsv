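# Per-residue coarse-grained parameters, HPS-Urry set (editable).
# Columns: code = one-letter amino-acid code; mass in amu; sigma = vdW
# diameter in nm; lambda0 = dimensionless hydropathy in [0, 1.2];
# charge in elementary charges (integer -1, 0, +1; assigned at pH 7 with
# neutral histidine). Replace this file (or pass your own via
# read_hps_params()) to use a different parameter set.
code	mass	sigma	lambda0	charge
A	71.08	0.504	0.602942	0
R	156.20	0.656	0.558824	1
N	114.10	0.568	0.588236	0
D	115.09	0.558	0.294118	-1
C	103.14	0.548	0.646060	0
Q	128.13	0.602	0.558824	0
E	129.12	0.592	0.000000	-1
G	57.05	0.450	0.573530	0
H	137.14	0.608	0.764707	0
I	113.16	0.618	0.705883	0
L	113.16	0.618	0.720589	0
K	128.17	0.636	0.382354	1
M	131.19	0.618	0.676471	0
F	147.18	0.636	0.823530	0
P	97.12	0.556	0.758824	0
S	87.08	0.518	0.588236	0
T	101.10	0.562	0.588236	0
W	186.21	0.678	1.000000	0
Y	163.18	0.646	0.897059	0
V	99.07	0.586	0.664707	0
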