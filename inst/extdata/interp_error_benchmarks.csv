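method,stage,mae_mm,sd_mm,median_mm
local_linear_embedding,filling,0.817,1.289,0.597
local_linear_embedding,maturity,0.879,1.364,0.673
biharmonic_spline,filling,0.572,0.863,0.331
biharmonic_spline,maturity,0.624,0.928,0.374
idw,filling,0.412,0.754,0.216
idw,maturity,0.428,0.785,0.243
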