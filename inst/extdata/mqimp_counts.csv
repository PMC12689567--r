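code,count,n,synthetic
X1-1,21,22,FALSE
X1-2,19,22,FALSE
X1-3,10,22,FALSE
X2-1,21,22,FALSE
X2-2,22,22,FALSE
X2-3,7,22,FALSE
X3-1,16,22,FALSE
X3-2,22,22,FALSE
X3-3,15,22,FALSE
X4-1,14,22,FALSE
X4-2,8,22,FALSE
X4-3,13,22,FALSE
X5-1,21,22,FALSE
X5-2,8,22,FALSE
X5-3,14,22,FALSE
X6-1,8,22,FALSE
X6-2,8,22,FALSE
X6-3,14,22,FALSE
X7-1,16,22,FALSE
X7-2,22,22,FALSE
X7-3,18,22,FALSE
X8-1,19,22,TRUE
X8-2,19,22,TRUE
X8-3,1,22,FALSE
X9-1,15,22,FALSE
X9-2,22,22,FALSE
X9-3,22,22,FALSE
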