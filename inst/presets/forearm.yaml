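# Forearm domain: gel pad / epidermis / dermis / muscle layers with bone,
# vessels, artery and vein; property table sampling (dermis & muscle 1%
# blood at N(80, 10)%, artery N(95, 5)%, vein N(70, 10)%, vessels U(0, 100)%,
# epidermis melanin N(2.2, 1)%, bone water N(19, 1)%); 26 wavelengths.
dataset_kind: forearm
n_phantoms: 48
wavelengths: forearm
profile: desk
model: layered
noise_frac: 0.01
compare_lu: true
seed: 1
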