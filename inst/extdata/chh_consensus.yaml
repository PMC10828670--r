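# Brachyuran CHH-superfamily reference peptides and consensus sequences.
# Mature peptides of the blackback land crab Gecarcinus lateralis:
#   Gl-MIH  - molt-inhibiting hormone (Type II; Gly at first-Cys + 5 = Gly12)
#   Gl-CHH  - eyestalk crustacean hyperglycemic hormone isoform (Type I);
#             the C-terminal RKKK basic extension is retained here.
# Consensus strings are in the degenerate motif grammar (x = unconserved site),
# derived from alignments of 33 brachyuran MIH and 48 eyestalk CHH mature
# peptides; each contains exactly six conserved cysteines.
peptides:
  - id: Gl-MIH
    family: MIH
    sequence: "AVINDECPNVIGNRDIFKKVDWICEDCANIFRIDGLATLCRKNCFRNIDFLWCVYASERQAEKDELTRYVSILRAGSV"
  - id: Gl-CHH
    family: CHH
    sequence: "QIYDRSCKGVYDRSLFNKLEHVCDDCYNLYRTSFVYSSCRENCYSNLVFRQCMEDLLLMDVFDEYAKAVQVVGRKKK"
consensus:
  - family: MIH
    pattern: "xVxNDxCPNxIGNRDxxKxVxWICxDCxNIxRxxGxAxxCRxxCFxNxDFxWCVxAxERxxxxxxLxxxVxILxAGxx"
  - family: CHH
    pattern: "QxxDxxCKGxYDRxxFxxLxxVCxDCYNLYRxxxVxxxCRxNCYxNxVxRQCxxDLLxxDxxxxxxxxxQxVGxKxx"
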