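event_name	exposure_events	exposure_total	nonexposure_events	nonexposure_total	printed_exposure_pct	printed_nonexposure_pct
Leukopenia	10	50	19	47	20	40
Hepatotoxicity	16	50	14	47	32	30
Nausea	20	50	29	47	40	62
Diarrhea	9	50	20	47	18	43
Fatigue	16	50	27	47	32	57
Appetite loss	18	50	28	47	36	60
Hair loss	7	50	12	47	14	26
Hand-foot syndrome	13	50	17	47	26	36
Rash	12	50	10	47	24	21
Hypertension	11	50	14	47	22	30
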