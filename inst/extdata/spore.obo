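format-version: 1.2

[Term]
id: CL:EukaryoticCell
name: eukaryotic cell
disjoint_from: CL:ProkaryoticCell

[Term]
id: CL:ProkaryoticCell
name: prokaryotic cell

[Term]
id: CL:FungalCell
name: fungal cell
is_a: CL:EukaryoticCell

[Term]
id: CL:Spore
name: spore
intersection_of: CL:FungalCell
intersection_of: CL:ProkaryoticCell

[Term]
id: GO:Sporulation
name: sporulation
namespace: biological_process

[Term]
id: GO:SporulationResultingInFormationOfACellularSpore
name: sporulation resulting in formation of a cellular spore
namespace: biological_process
intersection_of: GO:Sporulation
intersection_of: results_in_formation_of CL:Spore

[Term]
id: GO:SporeWallBiogenesis
name: spore wall biogenesis
namespace: biological_process
relationship: part_of GO:SporulationResultingInFormationOfACellularSpore

[Term]
id: GO:SporeWallAssembly
name: spore wall assembly
namespace: biological_process
relationship: part_of GO:SporeWallBiogenesis
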