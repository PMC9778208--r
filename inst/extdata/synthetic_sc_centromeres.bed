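chrI	151405	151525	CEN1
chrII	238147	238267	CEN2
chrIII	114325	114445	CEN3
chrIV	449651	449771	CEN4
chrV	151927	152047	CEN5
chrVI	148450	148570	CEN6
chrVII	496860	496980	CEN7
chrVIII	105526	105646	CEN8
chrIX	355569	355689	CEN9
chrX	436247	436367	CEN10
chrXI	440069	440189	CEN11
chrXII	150768	150888	CEN12
chrXIII	267971	268091	CEN13
chrXIV	628698	628818	CEN14
chrXV	326524	326644	CEN15
chrXVI	555897	556017	CEN16
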