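# SWC morphology written by mbggn
# columns: id type x y z radius parent (um)
# struct type codes: 1=SOMA 5=BASAL 6=ALPHA_LOBE 7=CALYX_LATERAL
#                    8=CALYX_MEDIAL 9=LATERAL_HORN
1 1 0 0 0 10 -1
2 5 54.574494 -2.3935434 -1.388585 9.8 1
3 5 103.74991 -4.33489 -3.2831449 9.6 2
4 5 155.24619 -4.5688005 -2.9778297 9.4 3
5 6 170.57648 23.018001 16.27535 5.724058 4
6 6 157.81205 28.72083 21.011834 4.5838348 4
7 9 162.69573 -55.603371 -26.219885 4.1355978 4
8 7 172.40287 -3.4276471 36.982741 5.7039731 4
9 7 168.63763 -2.4679089 21.926871 3.5624968 4
10 8 139.27684 8.3141831 25.630585 5.7936214 4
11 6 192.54714 68.72429 49.103415 3.7228958 5
12 6 181.04627 60.081249 38.738985 3.8471735 5
13 6 161.873 75.882965 57.848235 3.6974321 6
14 9 172.70685 -105.45495 -56.065382 2.5867903 7
15 9 172.59276 -106.65195 -49.472132 2.5981257 7
16 7 179.67404 3.7202583 71.082439 3.3418308 8
17 7 188.38962 -1.0479407 62.707838 3.3771963 8
18 7 179.99982 -7.696786 50.720948 2.1692039 9
19 8 127.68926 19.31745 48.59148 4.3800955 10
20 6 187.24905 101.33934 59.507118 2.9246405 12
21 6 201.7588 107.61089 73.130601 2.3669629 11
22 6 168.32196 104.54336 82.343373 2.1919159 13
23 9 178.47065 -149.09152 -81.30602 1.7974298 14
24 9 179.10498 -137.82947 -68.012002 1.8760797 15
25 7 202.71711 4.3794576 92.423542 2.688084 17
26 7 183.37694 11.791497 105.08678 2.6202627 16
27 7 187.47357 -17.50775 78.672144 1.5524554 18
28 8 110.09411 30.259609 75.991069 2.8478797 19
29 8 115.87697 39.452225 83.444264 2.8022299 19
30 6 194.57326 150.75599 81.965765 1.9486001 20
31 6 215.27041 156.44981 98.533037 1.5077554 21
32 9 172.20832 -201.40022 -101.56963 0.99307998 23
33 9 191.12129 -180.82764 -88.329893 1.1968757 24
34 7 181.28492 15.889475 136.77986 1.5284654 26
35 7 217.96275 15.816446 123.26702 1.710788 25
36 7 186.65724 17.168453 139.72241 1.5170392 26
37 7 195.48808 -21.790848 102.07758 0.84246447 27
38 8 96.518468 39.617546 96.600336 1.7485268 28
39 8 87.871496 46.350841 112.20971 1.4520395 28
40 8 106.91671 57.411836 120.22611 1.7690303 29
41 6 200.13557 195.34963 108.19099 1.0766015 30
42 9 203.4884 -231.68885 -118.48269 0.76240979 33
43 7 179.15351 16.591008 167.04625 0.82794802 34
44 7 235.4004 33.420153 147.85663 0.92232374 35
45 7 224.27639 17.176311 152.32438 0.93439344 35
46 7 181.48161 20.653304 169.21258 0.82284829 34
47 7 190.07936 25.614807 182.39862 0.85377721 36
48 8 70.628691 51.048976 131.16448 0.96638312 38
49 8 72.982936 59.9675 141.23948 0.67925999 39
50 8 70.466502 50.462235 126.85295 0.84505983 38
51 8 66.86232 59.793116 144.78587 0.66945362 39
52 8 100.568 72.54766 139.63247 1.2104679 40
53 7 174.05076 11.511387 202.51047 0.42192231 43
54 7 252.62492 59.346137 176.6153 0.50958387 44
55 7 175.54665 23.773626 199.71989 0.42192231 43
56 7 180.83888 21.006969 202.615 0.36369894 46
57 7 172.94606 23.325354 200.81779 0.41932349 46
58 7 229.09979 17.251059 184.65908 0.59520862 45
59 7 194.94894 26.809353 226.59263 0.54385608 47
60 8 53.168318 55.971237 159.22518 0.42714134 48
61 8 56.323051 58.823535 148.90105 0.54874905 50
62 8 54.912597 70.853566 179.35301 0.43268861 49
63 8 39.528002 57.500483 160.60523 0.42714134 48
64 8 51.452661 66.034875 169.6578 0.2958985 51
65 8 86.220292 93.453144 172.94328 0.66878351 52
66 8 49.455447 77.593476 178.18502 0.34115356 51
67 8 45.534267 71.609947 171.67396 0.25 61
68 8 41.134947 70.902322 184.54417 0.25 61
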