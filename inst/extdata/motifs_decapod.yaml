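# Default decapod CFRC motif library: conserved ECL2/ECL3 motifs distinguishing
# the 11 decapod subclades. ECL2 patterns carry the (C) anchor marker on the
# conserved extracellular-loop-2 cysteine; ECL3 patterns are unanchored.
# Grammar: uppercase = conserved residue; x = unconserved site; [AB] = either
# residue; '-' inside brackets = site may be deleted (indel).
motifs:
  - clade: A2
    subclade: "A2α1"
    region: ECL2
    pattern: "QYGIVYxxx[L-]PxGxDxPxxSx(C)xxKxxxx"
  - clade: A2
    subclade: "A2α1"
    region: ECL3
    pattern: "HxDxxNPxxVxLFNx"
  - clade: A2
    subclade: "A2β"
    region: ECL2
    pattern: "xxxVNxxxxPxGxDLPQSxW(C)xIPYxDxxxxxx"
  - clade: A2
    subclade: "A2β"
    region: ECL3
    pattern: "xxxTxxxQWTxxxxSVNTx"
  - clade: A24
    subclade: "A24α"
    region: ECL2
    pattern: "YxTTxxxxYxxxE[x-]Rxx(C)xxxWPDGxxxxSQxEx"
  - clade: A24
    subclade: "A24α"
    region: ECL3
    pattern: "xxxxIxxxxxIQx"
  - clade: A24
    subclade: "A24β1"
    region: ECL2
    pattern: "YSTTVSIxYxNxEIRRG(C)FLLWPDGxTSxSYxEY"
  - clade: A24
    subclade: "A24β1"
    region: ECL3
    pattern: "HNSQVLDxxxIQH"
  - clade: A24
    subclade: "A24β2"
    region: ECL2
    pattern: "xSTTVSxxYKxDEVRRG(C)ILRWPDGxTSxSxxEH"
  - clade: A24
    subclade: "A24β2"
    region: ECL3
    pattern: "HNSxxLxTAHIQH"
  - clade: A24
    subclade: "A24β3"
    region: ECL2
    pattern: "YATTxxxxxGxRTI(C)VIxWPDGLAxxSxxDY"
  - clade: A24
    subclade: "A24β3"
    region: ECL3
    pattern: "HHPQLSxRPYVQH"
  - clade: A34
    subclade: "A34α1"
    region: ECL2
    pattern: "YRVxTxHIWKDxxxTx(C)GExxxxx"
  - clade: A34
    subclade: "A34α1"
    region: ECL3
    pattern: "xFLxxxGxxKDxxxxxxYxx"
  - clade: A34
    subclade: "A34α2"
    region: ECL2
    pattern: "YRxYxxxxWxDLTExx(C)GEExxKxx"
  - clade: A34
    subclade: "A34α2"
    region: ECL3
    pattern: "xFxDxxxHxxSxxAEKxxxx"
  - clade: A34
    subclade: "A34β1"
    region: ECL2
    pattern: "YRxLxSxxWxNFTTxQ(C)xEFxPTxxxxxxxxxx[x-]CxxxYDxKx"
  - clade: A34
    subclade: "A34β1"
    region: ECL3
    pattern: "F[x-]xxxxxLPEWFSx"
  - clade: A34
    subclade: "A34β2"
    region: ECL2
    pattern: "YRxxYxxxWSNFTxWx(C)xExFPxxxxxxxGx[G-]CVVTxDAKx"
  - clade: A34
    subclade: "A34β2"
    region: ECL3
    pattern: "xxxx[x-]HxxEWxxx"
  - clade: A34
    subclade: "A34β3"
    region: ECL2
    pattern: "VRxTxVxxWxDLVEES(C)xDxxCxxxxxxxFx"
  - clade: A34
    subclade: "A34β3"
    region: ECL3
    pattern: "x[ED]xxxxPxWFxx"
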