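axis_id	gene
1	g00001
1	g00002
1	g00003
1	g00004
1	g00005
1	g00006
1	g00007
1	g00008
1	g00009
1	g00010
2	g00021
2	g00022
2	g00023
2	g00024
2	g00025
2	g00026
2	g00027
2	g00028
2	g00029
2	g00030
3	g00041
3	g00042
3	g00043
3	g00044
3	g00045
3	g00046
3	g00047
3	g00048
3	g00049
3	g00050
4	g00061
4	g00062
4	g00063
4	g00064
4	g00065
4	g00066
4	g00067
4	g00068
4	g00069
4	g00070
5	g00081
5	g00082
5	g00083
5	g00084
5	g00085
5	g00086
5	g00087
5	g00088
5	g00089
5	g00090
6	g00101
6	g00102
6	g00103
6	g00104
6	g00105
6	g00106
6	g00107
6	g00108
6	g00109
6	g00110
7	g00111
7	g00112
7	g00113
7	g00114
7	g00115
7	g00116
7	g00117
7	g00118
7	g00119
7	g00120
8	g00121
8	g00122
8	g00123
8	g00124
8	g00125
8	g00126
8	g00127
8	g00128
8	g00129
8	g00130
9	g00131
9	g00132
9	g00133
9	g00134
9	g00135
9	g00136
9	g00137
9	g00138
9	g00139
9	g00140
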