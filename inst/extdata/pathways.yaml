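# Pathway member definitions for reciprocal-best-hit presence calls.
# Each member lists the human query identifiers used for the forward search;
# a member is called present in a species when the reciprocal search returns
# one of these identifiers as the unique best hit.
tlr_nfkb:
  pathway_id: tlr_nfkb
  members:
    - member_name: MYD88
      query_ids: [MYD88_HUMAN]
    - member_name: IRAK1
      query_ids: [IRAK1_HUMAN]
    - member_name: IRAK4
      query_ids: [IRAK4_HUMAN]
    - member_name: TRAF6
      query_ids: [TRAF6_HUMAN]
    - member_name: TAB1
      query_ids: [TAB1_HUMAN]
    - member_name: TAK1
      query_ids: [M3K7_HUMAN]
    - member_name: IKK
      query_ids: [IKKA_HUMAN, IKKB_HUMAN]
    - member_name: NEMO
      query_ids: [NEMO_HUMAN]
    - member_name: NFKB
      query_ids: [NFKB1_HUMAN, NFKB2_HUMAN]
    - member_name: IKBA
      query_ids: [IKBA_HUMAN]
rlr_nfkb:
  pathway_id: rlr_nfkb
  members:
    - member_name: MAVS
      query_ids: [MAVS_HUMAN]
    - member_name: TRAF3
      query_ids: [TRAF3_HUMAN]
    - member_name: TBK1
      query_ids: [TBK1_HUMAN]
    - member_name: IRF3
      query_ids: [IRF3_HUMAN]
nlr_nfkb:
  pathway_id: nlr_nfkb
  members:
    - member_name: RIPK2
      query_ids: [RIPK2_HUMAN]
    - member_name: CARD9
      query_ids: [CARD9_HUMAN]
    - member_name: ASC
      query_ids: [ASC_HUMAN]
    - member_name: CASP1
      query_ids: [CASP1_HUMAN]
ctl_nfkb:
  pathway_id: ctl_nfkb
  members:
    - member_name: SYK
      query_ids: [KSYK_HUMAN]
    - member_name: BCL10
      query_ids: [BCL10_HUMAN]
    - member_name: MALT1
      query_ids: [MALT1_HUMAN]
lectin_complement:
  pathway_id: lectin_complement
  members:
    - member_name: MBL
      query_ids: [MBL2_HUMAN]
    - member_name: MASP
      query_ids: [MASP1_HUMAN, MASP2_HUMAN]
    - member_name: C3
      query_ids: [CO3_HUMAN]
    - member_name: BF_C2
      query_ids: [CFAB_HUMAN, CO2_HUMAN]
    - member_name: C6
      query_ids: [CO6_HUMAN]
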