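step,delay_days
1,4.16666666666667e-02
2,6.27774342870046e-02
3,9.45841501358203e-02
4,1.42506006473847e-01
5,2.14707874965970e-01
6,3.23491428277885e-01
7,4.87391085146981e-01
8,7.34331883677275e-01
9,1.10638731773766e+00
10,1.66694777124603e+00
11,2.51152090006239e+00
12,3.78400411833853e+00
13,5.70120167713805e+00
14,8.58976352744386e+00
15,1.29418395692404e+01
16,1.94989315946626e+01
17,2.93782295244176e+01
18,4.42629569625039e+01
19,6.66891569294904e+01
20,1.00477780003124e+02
21,1.51385693554805e+02
22,2.28086530299105e+02
23,3.43648492022471e+02
24,5.17760895018454e+02
25,7.80088813521641e+02
26,1.17532738149317e+03
27,1.77081689897771e+03
28,2.66801619623738e+03
29,4.01978907446294e+03
30,6.05644906727320e+03
31,9.12499999999999e+03
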