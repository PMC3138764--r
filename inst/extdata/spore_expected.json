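{
  "unsatisfiable": ["CL:Spore", "GO:SporeWallAssembly", "GO:SporeWallBiogenesis", "GO:SporulationResultingInFormationOfACellularSpore"]
}
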