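# Reference specimens per species (holotype / deposited reference
# sequence), with per-marker overrides where the designated specimen
# lacks a marker. Used together with pontohedyle_specimens.tsv when the
# deposited supplementary alignments are available under
# inst/extdata/deposited/.
references:
  P_milaschewitchii:
    default: ZSM_Mol_20071381
    by_marker:
      18S: ZSM_Mol_20080054
      28S: ZSM_Mol_20080054
  P_brasilensis:
    default: ZSM_Mol_20110722
    by_marker:
      28S: ZSM_Mol_20090198
  P_verrucosa:
    default: ZSM_Mol_20071820
  P_kepii:
    default: ZSM_Mol_20081013
  P_joni:
    default: ZSM_Mol_20090197
  P_neridae:
    default: AM_C_476062.001
  P_liliae:
    default: ZSM_Mol_20090471
  P_wiggi:
    default: ZSM_Mol_20100595
  P_wenzli:
    default: ZSM_Mol_20100379
  P_peteryalli:
    default: ZSM_Mol_20071133
  P_martynovi:
    default: AM_C_476054.001
  P_yurihookeri:
    default: ZSM_Mol_20080565
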