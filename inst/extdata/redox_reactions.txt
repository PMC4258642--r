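# Redox reaction registry: photoferrotrophic primary production, anaerobic
# organic-matter degradation (Fe(III) respiration, sulfate respiration,
# methanogenesis), and the net combinations of primary production with
# sulfate respiration and with methanogenesis.
# Syntax: id: coeff Species + ... -> coeff Species + ...
photoferrotrophy: 2 CO2 + 8 Fe^2+ + 14 H2O -> 2 CH2O + 8 FeOOH + 16 H+
feIII_respiration: 2 CH2O + 8 FeOOH + 16 H+ -> 2 CO2 + 8 Fe^2+ + 14 H2O
sulfate_respiration: 2 CH2O + SO4^2- + 2 H+ -> 2 CO2 + H2S + 2 H2O
methanogenesis: 2 CH2O -> CO2 + CH4
photoferrotrophy + sulfate_respiration: 8 Fe^2+ + SO4^2- + 12 H2O -> 8 FeOOH + H2S + 14 H+
photoferrotrophy + methanogenesis: CO2 + 8 Fe^2+ + 14 H2O -> CH4 + 8 FeOOH + 16 H+
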