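# structural-state substitution matrix (half-bit-like units)
# background: A=0.156317 B=0.018415 C=0.018844 D=0.047537 E=0.022698 F=0.002570 G=0.043255 H=0.032976 I=0.008137 J=0.039400 K=0.012420 L=0.169165 M=0.030835 N=0.004283 O=0.006424 P=0.041542 Q=0.011135 R=0.015846 S=0.025696 T=0.292505
 	A	B	C	D	E	F	G	H	I	J	K	L	M	N	O	P	Q	R	S	T	X
A	4	-9	-10	2	-10	-4	-12	-9	-7	-5	-2	1	0	-5	-6	-10	-1	-9	1	-17	0
B	-9	10	-3	-6	1	2	-1	1	-1	-6	-2	-10	-5	6	0	-6	1	-3	-4	-3	0
C	-10	-3	10	2	-4	2	-3	-5	-1	3	-2	-3	0	1	0	-1	-2	-3	1	-7	0
D	2	-6	2	6	-7	0	-9	-8	-4	1	-5	-1	-1	-2	-3	0	-5	-6	1	-14	0
E	-10	1	-4	-7	10	2	1	0	-2	-1	-3	-10	-5	0	-1	-6	-2	-3	-5	-5	0
F	-4	2	2	0	2	8	0	1	5	0	3	-4	1	7	10	0	4	3	1	-6	0
G	-12	-1	-3	-9	1	0	8	0	-3	-5	-5	-6	-3	2	-3	-3	-4	-5	-3	-14	0
H	-9	1	-5	-8	0	1	0	9	2	-1	-4	-4	-4	-1	-2	2	-4	-5	-4	-5	0
I	-7	-1	-1	-4	-2	5	-3	2	12	-3	7	-7	-2	3	2	-3	0	-1	-2	-9	0
J	-5	-6	3	1	-1	0	-5	-1	-3	8	1	-9	-2	-1	-2	-3	-4	-5	-6	-10	0
K	-2	-2	-2	-5	-3	3	-5	-4	7	1	11	-7	-4	2	5	-5	-1	-2	4	-10	0
L	1	-10	-3	-1	-10	-4	-6	-4	-7	-9	-7	4	-1	-6	-7	-10	-4	-7	2	-18	0
M	0	-5	0	-1	-5	1	-3	-4	-2	-2	-4	-1	8	-1	-2	1	-3	4	0	-13	0
N	-5	6	1	-2	0	7	2	-1	3	-1	2	-6	-1	11	4	-1	7	1	0	-7	0
O	-6	0	0	-3	-1	10	-3	-2	2	-2	5	-7	-2	4	13	-3	1	0	-1	-8	0
P	-10	-6	-1	0	-6	0	-3	2	-3	-3	-5	-10	1	-1	-3	8	0	0	-7	-9	0
Q	-1	1	-2	-5	-2	4	-4	-4	0	-4	-1	-4	-3	7	1	0	11	5	0	-10	0
R	-9	-3	-3	-6	-3	3	-5	-5	-1	-5	-2	-7	4	1	0	0	5	11	-2	-11	0
S	1	-4	1	1	-5	1	-3	-4	-2	-6	4	2	0	0	-1	-7	0	-2	6	-7	0
T	-17	-3	-7	-14	-5	-6	-14	-5	-9	-10	-10	-18	-13	-7	-8	-9	-10	-11	-7	3	0
X	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
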