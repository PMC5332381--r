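og_id	clade	status
OG-SCR-3	Brassicales	absent
OG-SHR-2	Brassicales	absent
OG-SHR-2	Poales	absent
OG-SCL32-2	Brassicales	absent
OG-NSP2-2	Brassicales	absent
OG-NSP2-2	Malvales	absent
OG-NSP2-3	Brassicales	absent
OG-NSP2-3	monocots	absent
OG-DELLA-2	Brassicales	absent
OG-PAT-2	Brassicales	present
OG-RAD1-1	Brassicales	absent
OG-RAD1-2	Brassicales	absent
OG-RAD1-2	Poales	absent
OG-RAM1	Brassicales	absent
OG-SCLA	Brassicales	absent
OG-SCLB	Brassicales	absent
OG-SCLB	Poales	absent
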