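chr1	173450000	173450018	Nr1d1:MA1531.2
chr1	173250000	173250013	Dlx3:MA0611.1
chr1	173389772	173389786	Mef2c:MA0497.1
chr1	173595091	173595099	Foxo1:MA0480.1
chr1	173724585	173724606	Egr1:MA0162.4
chr1	173914824	173914833	Nfya:MA0060.3
chr1	174082755	174082772	Rora:MA0071.1
chr1	174210357	174210379	Klf4:MA0039.4
chr1	174396867	174396878	Stat3:MA0144.2
chr1	174521781	174521790	Creb1:MA0018.4
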