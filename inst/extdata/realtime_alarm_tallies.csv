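combination,no_event_alarmed,no_event_total,printed_percent
WF,937,2023,46
PTSOLID,1065,2033,52
WF+PTSOLID,1278,2003,64
WF+FIXED,1150,2023,57
WF+PTSOLID+FIXED,1117,2003,56
WF+AF,622,2023,31
AF+WF,1007,2023,50
WF+AF+FIXED,734,2023,36
PTSOLID+WF,883,2003,44
PTSOLID+FIXED,1078,2033,53
PTSOLID+WF+FIXED,901,2003,45
WF+AF+PTSOLID+PTSLATTED,553,2003,28
WF+AF+PTSOLID+PTSLATTED+FIXED,729,2003,36
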