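!Series_title	"synthetic 3x2 example (handcrafted)"
!Series_platform_id	"SYNTH0"
!series_matrix_table_begin
"ID_REF"	"GSM_X"	"GSM_Y"
"P1"	1.5	-2.25
"P2"	0.125	3
"P3"	-4.5	0.0625
!series_matrix_table_end
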