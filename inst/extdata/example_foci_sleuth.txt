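// Reference=Talairach
// Smith 2010: ASD < TDC
// Subjects=24
// Direction=decrease
-38	-18	8
-4	-40	40
41	-21	43

// Lee 2015: ASD > TDC
// Subjects=31
// Direction=increase
31	41	19
-29	39	15
5	21	-13
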