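residue	formula	exchangeable_H
A	C3H5NO	4.00
R	C6H12N4O	3.43
N	C4H6N2O2	1.89
D	C4H5NO3	1.89
C	C3H5NOS	1.62
E	C5H7NO3	3.95
Q	C5H8N2O2	3.95
G	C2H3NO	2.06
H	C6H7N3O	2.88
I	C6H11NO	1.00
L	C6H11NO	0.60
K	C6H12N2O	0.54
M	C5H9NOS	1.12
F	C9H9NO	0.32
P	C5H7NO	2.59
S	C3H5NO2	2.61
T	C4H7NO2	0.20
W	C11H10N2O	0.08
Y	C9H9NO2	0.42
V	C5H9NO	0.56
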