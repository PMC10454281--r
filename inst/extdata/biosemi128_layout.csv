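label,x,y,z
A1,0.000000,0.000000,1.000000
A2,0.000000,-0.190809,0.981627
A3,0.000000,-0.390731,0.920505
A4,0.000000,-0.559193,0.829038
A5,-0.281068,-0.662156,0.694658
A6,-0.508650,-0.508650,0.694658
A7,-0.593030,-0.593030,0.544639
A8,-0.548745,-0.755282,0.358368
A9,-0.578855,-0.796726,0.173648
A10,-0.587427,-0.808524,-0.034899
A11,-0.572720,-0.788282,-0.224951
A12,-0.532714,-0.733218,-0.422618
A13,-0.280065,-0.861950,-0.422618
A14,-0.301097,-0.926681,-0.224951
A15,-0.308829,-0.950477,-0.034899
A16,-0.304322,-0.936608,0.173648
A17,-0.288492,-0.887888,0.358368
A18,-0.327695,-0.772000,0.544639
A19,0.000000,-0.719340,0.694658
A20,0.000000,-0.838671,0.544639
A21,0.000000,-0.933580,0.358368
A22,0.000000,-0.984808,0.173648
A23,0.000000,-0.999391,-0.034899
A24,0.000000,-0.974370,-0.224951
A25,0.000000,-0.906308,-0.422618
A26,0.280065,-0.861950,-0.422618
A27,0.301097,-0.926681,-0.224951
A28,0.308829,-0.950477,-0.034899
A29,0.304322,-0.936608,0.173648
A30,0.288492,-0.887888,0.358368
A31,0.327695,-0.772000,0.544639
A32,0.281068,-0.662156,0.694658
B1,0.181470,-0.058963,0.981627
B2,0.276289,-0.276289,0.920505
B3,0.508650,-0.508650,0.694658
B4,0.593030,-0.593030,0.544639
B5,0.548745,-0.755282,0.358368
B6,0.578855,-0.796726,0.173648
B7,0.587427,-0.808524,-0.034899
B8,0.572720,-0.788282,-0.224951
B9,0.532714,-0.733218,-0.422618
B10,0.788282,-0.572720,-0.224951
B11,0.808524,-0.587427,-0.034899
B12,0.796726,-0.578855,0.173648
B13,0.755282,-0.548745,0.358368
B14,0.950477,-0.308829,-0.034899
B15,0.936608,-0.304322,0.173648
B16,0.887888,-0.288492,0.358368
B17,0.777602,-0.314172,0.544639
B18,0.666960,-0.269469,0.694658
B19,0.484275,-0.279596,0.829038
B20,0.390731,0.000000,0.920505
B21,0.559193,0.000000,0.829038
B22,0.719340,0.000000,0.694658
B23,0.838671,0.000000,0.544639
B24,0.933580,0.000000,0.358368
B25,0.984808,0.000000,0.173648
B26,0.999391,0.000000,-0.034899
B27,0.950477,0.308829,-0.034899
B28,0.936608,0.304322,0.173648
B29,0.887888,0.288492,0.358368
B30,0.777602,0.314172,0.544639
B31,0.666960,0.269469,0.694658
B32,0.484275,0.279596,0.829038
C1,0.112155,0.154368,0.981627
C2,0.276289,0.276289,0.920505
C3,0.508650,0.508650,0.694658
C4,0.593030,0.593030,0.544639
C5,0.755282,0.548745,0.358368
C6,0.796726,0.578855,0.173648
C7,0.808524,0.587427,-0.034899
C8,0.587427,0.808524,-0.034899
C9,0.578855,0.796726,0.173648
C10,0.548745,0.755282,0.358368
C11,0.279596,0.484275,0.829038
C12,0.281068,0.662156,0.694658
C13,0.327695,0.772000,0.544639
C14,0.288492,0.887888,0.358368
C15,0.304322,0.936608,0.173648
C16,0.308829,0.950477,-0.034899
C17,0.000000,0.999391,-0.034899
C18,0.000000,0.984808,0.173648
C19,0.000000,0.933580,0.358368
C20,0.000000,0.838671,0.544639
C21,0.000000,0.719340,0.694658
C22,0.000000,0.559193,0.829038
C23,0.000000,0.390731,0.920505
C24,-0.279596,0.484275,0.829038
C25,-0.281068,0.662156,0.694658
C26,-0.327695,0.772000,0.544639
C27,-0.288492,0.887888,0.358368
C28,-0.304322,0.936608,0.173648
C29,-0.308829,0.950477,-0.034899
C30,-0.587427,0.808524,-0.034899
C31,-0.578855,0.796726,0.173648
C32,-0.548745,0.755282,0.358368
D1,-0.112155,0.154368,0.981627
D2,-0.276289,0.276289,0.920505
D3,-0.508650,0.508650,0.694658
D4,-0.593030,0.593030,0.544639
D5,-0.755282,0.548745,0.358368
D6,-0.796726,0.578855,0.173648
D7,-0.808524,0.587427,-0.034899
D8,-0.950477,0.308829,-0.034899
D9,-0.936608,0.304322,0.173648
D10,-0.887888,0.288492,0.358368
D11,-0.777602,0.314172,0.544639
D12,-0.666960,0.269469,0.694658
D13,-0.484275,0.279596,0.829038
D14,-0.390731,-0.000000,0.920505
D15,-0.181470,-0.058963,0.981627
D16,-0.276289,-0.276289,0.920505
D17,-0.484275,-0.279596,0.829038
D18,-0.559193,-0.000000,0.829038
D19,-0.719340,-0.000000,0.694658
D20,-0.838671,-0.000000,0.544639
D21,-0.933580,-0.000000,0.358368
D22,-0.984808,-0.000000,0.173648
D23,-0.999391,-0.000000,-0.034899
D24,-0.950477,-0.308829,-0.034899
D25,-0.936608,-0.304322,0.173648
D26,-0.887888,-0.288492,0.358368
D27,-0.777602,-0.314172,0.544639
D28,-0.666960,-0.269469,0.694658
D29,-0.755282,-0.548745,0.358368
D30,-0.796726,-0.578855,0.173648
D31,-0.808524,-0.587427,-0.034899
D32,-0.788282,-0.572720,-0.224951
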