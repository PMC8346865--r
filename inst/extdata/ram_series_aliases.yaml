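# Editable vocabulary mapping RAM-style series/parameter ids to the roles
# understood by read_ram_long(). Extend the lists for other database
# versions; ids not listed here are ignored on read.
total_biomass:
  - TB-MT
  - TB-E00
  - TB
spawning_biomass:
  - SSB-MT
  - SSB-E00
  - SSB
b_ratio_total:
  - TBdivTBmsy-dimensionless
  - TBdivTBmsy
  - BdivBmsypref-dimensionless
b_ratio_spawning:
  - SSBdivSSBmsy-dimensionless
  - SSBdivSSBmsy
exploitation:
  - ER-ratio
  - ER
u_ratio:
  - ERdivERmsy-dimensionless
  - ERdivERmsy
  - UdivUmsypref-dimensionless
  - FdivFmsy-dimensionless
catch:
  - TC-MT
  - TL-MT
  - TC
b_msy:
  - TBmsy-MT
  - SSBmsy-MT
  - Bmsy
u_msy:
  - ERmsy-ratio
  - Umsy
  - Fmsy-1/yr
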