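region	region_start	region_end	label	start	end
MP-Dis	75	384	MP	75	285
MP-Dis	75	384	Dis	286	383
MP-Dis	75	384	TSP1	384	384
Cys-Spa	440	684	Cys	440	549
Cys-Spa	440	684	Spa	550	680
Cys-Spa	440	684	TSP2	681	684
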