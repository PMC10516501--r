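protein_id	is_mito	process_group	compartment	complex	submodule
MPQ00001	TRUE	translation	inner membrane	NA	NA
MPQ00002	TRUE	translation	IMS	NA	NA
MPQ00003	TRUE	calcium signalling	matrix	NA	NA
MPQ00004	TRUE	import & sorting	matrix	NA	NA
MPQ00005	TRUE	import & sorting	inner membrane	NA	NA
MPQ00006	TRUE	translation	inner membrane	NA	NA
MPQ00007	TRUE	oxidative phosphorylation	outer membrane	CIII	NA
MPQ00008	TRUE	import & sorting	inner membrane	NA	NA
MPQ00009	TRUE	morphology	outer membrane	NA	NA
MPQ00010	TRUE	metabolism	matrix	NA	NA
MPQ00011	TRUE	transcription	outer membrane	NA	NA
MPQ00012	TRUE	calcium signalling	matrix	NA	NA
MPQ00013	TRUE	transcription	matrix	NA	NA
MPQ00014	TRUE	proteostasis	matrix	NA	NA
MPQ00015	TRUE	transcription	outer membrane	NA	NA
MPQ00016	TRUE	proteostasis	inner membrane	NA	NA
MPQ00017	TRUE	translation	IMS	NA	NA
MPQ00018	TRUE	proteostasis	outer membrane	NA	NA
MPQ00019	TRUE	transcription	inner membrane	NA	NA
MPQ00020	TRUE	transcription	inner membrane	NA	NA
MPQ00021	TRUE	oxidative phosphorylation	matrix	CII	NA
MPQ00022	TRUE	metabolism	matrix	NA	NA
MPQ00023	TRUE	import & sorting	outer membrane	NA	NA
MPQ00024	TRUE	metabolism	IMS	NA	NA
MPQ00025	TRUE	import & sorting	IMS	NA	NA
MPQ00026	TRUE	morphology	matrix	NA	NA
MPQ00027	TRUE	transcription	outer membrane	NA	NA
MPQ00028	TRUE	translation	IMS	NA	NA
MPQ00029	TRUE	calcium signalling	matrix	NA	NA
MPQ00030	TRUE	metabolism	inner membrane	NA	NA
NMITO001	FALSE	NA	NA	NA	NA
NMITO002	FALSE	NA	NA	NA	NA
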