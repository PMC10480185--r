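from,to
u01,u03
u01,u05
u01,u06
u01,u20
u01,u22
u01,u37
u02,u09
u03,u04
u03,u09
u04,u11
u04,u12
u04,u20
u05,u15
u05,u18
u05,u19
u06,u14
u07,u11
u07,u16
u07,u18
u07,u20
u08,u16
u09,u16
u10,u13
u11,u16
u11,u19
u12,u15
u13,u19
u13,u20
u13,u24
u13,u31
u13,u34
u14,u15
u14,u16
u14,u19
u15,u17
u16,u18
u16,u19
u16,u38
u17,u19
u18,u20
u18,u25
u20,u25
u21,u25
u21,u26
u21,u32
u21,u33
u21,u34
u22,u25
u22,u26
u22,u27
u22,u33
u23,u24
u23,u25
u23,u32
u23,u39
u24,u25
u24,u37
u24,u38
u24,u40
u25,u26
u25,u27
u25,u32
u25,u36
u25,u39
u26,u32
u26,u35
u26,u38
u27,u30
u27,u33
u27,u34
u27,u35
u27,u38
u28,u29
u28,u34
u28,u35
u28,u38
u29,u31
u29,u33
u29,u34
u29,u35
u29,u36
u30,u36
u30,u37
u30,u40
u32,u36
u32,u37
u32,u39
u32,u40
u33,u36
u34,u39
u34,u40
u37,u38
u38,u39
u38,u40
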