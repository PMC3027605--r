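clone_id	chromosome	arm	position_bp	in_lm_pam
GS-82-O2	20	p	1500000	FALSE
GS-1061-L1	20	p	2775000	FALSE
RP5-852M4	20	p	4050000	FALSE
RP11-314N13	20	p	5325000	FALSE
RP4-686C3	20	p	6600000	FALSE
RP4-741H3	20	p	7875000	FALSE
RP4-599I11	20	p	9150000	FALSE
RP4-764O22	20	p	10425000	FALSE
RP5-1140M3	20	p	11700000	FALSE
RP4-811H13	20	p	12975000	FALSE
RP11-204H22	20	p	14250000	FALSE
RP4-742J24	20	p	15525000	FALSE
RP11-104O6	20	p	16800000	FALSE
RP11-526K24	20	p	18075000	FALSE
RP5-822J19	20	p	19350000	FALSE
RP3-348M17	20	p	20625000	FALSE
RP11-504H3	20	p	21900000	FALSE
RP1-167O22	20	p	23175000	FALSE
RP4-788L20	20	p	24450000	FALSE
RP1-234M6	20	p	25725000	FALSE
RP5-1025A1	20	p	2.7e+07	FALSE
RP11-348I14	20	q	2.8e+07	TRUE
RP3-324O17	20	q	28802326	FALSE
RP5-857M17	20	q	29604651	FALSE
RP1-310O13	20	q	30406977	FALSE
RP11-410N8	20	q	31209302	FALSE
RP5-1085F17	20	q	32011628	TRUE
RP4-733O23	20	q	32813953	FALSE
RP5-1137F22	20	q	33616279	TRUE
RP11-353C18	20	q	34418605	TRUE
RP11-234K24	20	q	35220930	TRUE
RP3-469A13	20	q	36023256	TRUE
RP4-633O20	20	q	36825581	TRUE
RP11-122O1	20	q	37627907	TRUE
RP4-600E6	20	q	38430233	TRUE
RP5-892M9	20	q	39232558	TRUE
RP4-796I11	20	q	40034884	TRUE
RP1-128O17	20	q	40837209	TRUE
RP1-232N11	20	q	41639535	TRUE
RP1-138B7	20	q	42441860	TRUE
RP5-1028D15	20	q	43244186	TRUE
RP3-337O18	20	q	44046512	TRUE
RP5-1005L2	20	q	44848837	FALSE
RP11-347D21	20	q	45651163	TRUE
RP1-155G6	20	q	46453488	TRUE
RP3-470L14	20	q	47255814	TRUE
RP4-791K14	20	q	48058140	TRUE
RP5-1185N5	20	q	48860465	FALSE
RP4-530I15	20	q	49662791	FALSE
RP5-994O24	20	q	50465116	TRUE
RP4-715N11	20	q	51267442	TRUE
RP4-724E16	20	q	52069767	FALSE
RP5-1075G21	20	q	52872093	TRUE
RP5-1162C3	20	q	53674419	TRUE
RP11-6L15	20	q	54476744	TRUE
RP5-1167H4	20	q	55279070	TRUE
RP5-1153D9	20	q	56081395	FALSE
RP11-46O3	20	q	56883721	TRUE
RP13-379L11	20	q	57686047	TRUE
RP1-309F20	20	q	58488372	TRUE
RP5-827E24	20	q	59290698	TRUE
RP5-1107C24	20	q	60093023	TRUE
RP4-563E14	20	q	60895349	TRUE
RP13-152O15	20	q	61697674	TRUE
GS-81-F12	20	q	62500000	TRUE
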