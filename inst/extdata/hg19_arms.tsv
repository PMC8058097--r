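chromosome	length	cen_start	cen_end	acrocentric
1	249250621	121535434	124535434	FALSE
2	243199373	92326171	95326171	FALSE
3	198022430	90504854	93504854	FALSE
4	191154276	49660117	52660117	FALSE
5	180915260	46405641	49405641	FALSE
6	171115067	58830166	61830166	FALSE
7	159138663	58054331	61054331	FALSE
8	146364022	43838887	46838887	FALSE
9	141213431	47367679	50367679	FALSE
10	135534747	39254935	42254935	FALSE
11	135006516	51644205	54644205	FALSE
12	133851895	34856694	37856694	FALSE
13	115169878	16000000	19000000	TRUE
14	107349540	16000000	19000000	TRUE
15	102531392	17000000	20000000	TRUE
16	90354753	35335801	38335801	FALSE
17	81195210	22263006	25263006	FALSE
18	78077248	15460898	18460898	FALSE
19	59128983	24681782	27681782	FALSE
20	63025520	26369569	29369569	FALSE
21	48129895	11288129	14288129	TRUE
22	51304566	13000000	16000000	TRUE
X	155270560	58632012	61632012	FALSE
Y	59373566	10104553	13104553	FALSE
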