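# Abundant plasma proteins removed by the Top-14 depletion kit; applied as an
# a-priori exclusion list (by feature id) before missingness filtering.
human serum albumin
albumin
IgG
IgA
IgM
IgD
IgE
kappa light chain
lambda light chain
alpha-1 acid glycoprotein
alpha-1 antitrypsin
alpha-2 macroglobulin
apolipoprotein A1
fibrinogen
haptoglobin
transferrin
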