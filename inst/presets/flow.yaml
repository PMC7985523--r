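# Blood flow phantom domain: one blood tube (150 g/L hemoglobin, radius
# U(0.5, 2.5) mm, sO2 U(0, 1)) in agar (mu_s' = 5 cm^-1, water U(50, 100)%),
# pencil-beam illumination, the 17 acquisition wavelengths.
dataset_kind: flow
n_phantoms: 96
wavelengths: flow
profile: desk
model: layered
noise_frac: 0.01
compare_lu: true
seed: 1
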