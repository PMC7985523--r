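# Generic tissue domain: random vessel tubes (100% blood volume) in a
# homogeneous background (0.5% blood volume, mu_s' = 10 cm^-1); one shared
# oxygenation per phantom drawn uniformly from [0, 1]; 26 wavelengths
# 700-950 nm. "desk" profile trains 40 epochs x 100 batches x 512 spectra;
# switch profile to "paper" for 100 epochs x 500 batches x 1e4.
dataset_kind: generic
n_phantoms: 96
wavelengths: generic
profile: desk
model: layered
noise_frac: 0.01
compare_lu: true
seed: 1
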