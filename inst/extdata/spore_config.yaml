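root_map:
  PATO: Quality
  FMA: MaterialObject
  MA: MaterialObject
  CL: MaterialObject
  PR: MaterialObject
  CHEBI: MaterialObject
  UBERON: MaterialObject
  GO: namespace
mf_mode: function
strip_asserted_isa: no
add_quality_constraints: no
functional_inheres_in: yes
synonyms:
  partof: part_of
  haspart: has_part
  inheresin: inheres_in
  inheres_in_part_of: inheres_in_part_of
  quality_of: inheres_in
  has_agent_in: has_agent
  towards: towards
disambiguate: []
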