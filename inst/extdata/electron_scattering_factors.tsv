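# Electron atomic scattering factors, neutral atoms.
# 5-Gaussian parameterization f(s) = sum_i a_i * exp(-b_i * s^2), s = sin(theta)/lambda in 1/Angstrom, f in Angstrom.
# Source: L.-M. Peng, G. Ren, S. L. Dudarev & M. J. Whelan (1996), Acta Cryst. A52, 257-276
# (the parameterization reproduced in International Tables for Crystallography Vol. C, sec. 4.3.2).
element	a1	a2	a3	a4	a5	b1	b2	b3	b4	b5
H	0.0349	0.1201	0.1970	0.0573	0.1195	0.5347	3.5867	12.3471	18.9525	38.6269
C	0.0893	0.2563	0.7570	1.0487	0.3575	0.2465	1.7100	6.4094	18.6113	50.2523
N	0.1022	0.3219	0.7982	0.8197	0.1715	0.2451	1.7481	6.1925	17.3894	48.1431
O	0.0974	0.2921	0.6910	0.6990	0.2039	0.2067	1.3815	4.6943	12.7105	32.4726
F	0.1083	0.3175	0.6487	0.5846	0.1421	0.2057	1.3439	4.2788	11.3932	28.7881
Na	0.2142	0.6853	0.7692	1.6589	1.4482	0.3334	2.3446	10.0830	48.3037	138.2700
Al	0.2390	0.6573	1.2011	2.5586	1.2312	0.3138	2.1063	10.4163	34.4552	98.5344
Si	0.2519	0.6372	1.3795	2.5082	1.0500	0.3075	2.0174	9.6746	29.3744	80.4732
P	0.2548	0.6106	1.4541	2.3204	0.8477	0.2908	1.8740	8.5176	24.3434	63.2996
S	0.2497	0.5628	1.3899	2.1865	0.7715	0.2681	1.6711	7.0267	19.5377	50.3888
Co	0.4118	1.3161	1.6493	2.1930	1.2830	0.2742	2.0372	7.7205	29.9680	84.9383
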