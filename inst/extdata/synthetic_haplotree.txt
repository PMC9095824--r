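rCRS
	L0	T255G C905G T970C
	L1	T1364C A1586T
	L2	G1648C A1773T
	L3	A1835T T1932G A2036C
		M	C10400T T14783C G15043A
			M2	C2043G T2161A
			M3	A2231T C2301A
			M4	C2434G C2452A
			M5	C2461G T2519C
			M6	G2533C G2556C
			M7	C2840A C3282G
			M8	T3326C A3515C
				C	G3520C C4027A
				D	C4158T C4204A
			M9	G4303A
				E	T4383C T4395A
			M10	T4476A
			M11	T4651G
			M12	T4943C
			M18	C5046T C5244A
			M25	A5341T C5480G
			M30	T5513C T5904A
			M33	A5917G
			M35	T6076G
			M37	A6379C
			M39	G6520C G6778T C7058G
			M40	G7085A
			M65	C7120T A7438T
			M67	C7773G C8190G
			G	T8372A T8405C
		N	G8701A C10873T
			R	T12705C
				R0	A10121G T10348C
					HV	A10451T G10520C
						H	G2706A T7028C
						HV0	C10551T
							HV0e	G10743A G10850C
				JT	C10901T
					J	A11056T G11389C
					T	C11636A
				R1	T11649A
				R2	C11660A
				R5	C11762T T11796C
				R6	A11812C
				R7	T11851C
				R8	T12047A
				R22	G12224C
				R30	A12232T C12284T
				R31	T12960A T12980G
				R32	A13242G C13368A A13403C
				B	A13477T
				F	T13549A
				U	A11467G G12308A
					U1	A13691G
					U2	T13739G
						U2a	G13779C C13969A
						U2b	T14508G G14523T
					U3	G14536T
					U4	T14679A
					U5	G15306A
					U7	T15501G A15503G
					U8	A16095G
						K	G9055A
					U9	T16383C
			N5	T8431A T8437C
			N9	T8793C C9135T
			A	C9147A T9151G
			W	A9384G G9397C
			X	C9617G T9876C
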