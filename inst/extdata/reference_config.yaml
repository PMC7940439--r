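# Reference biophysical parameters of the diffusion-reaction model.
# Units: nm, ms, mM; diffusion coefficients in um^2/ms.
R: 300            # bouton (simulation domain) radius, nm
rho: 5            # sensor radius, nm
CD: 15            # coupling distance r - rho, nm
D0: 0.22          # free Ca2+ diffusion coefficient, um^2/ms
k_on: 635         # sensor forward rate constant (5 * 127), mM^-1 ms^-1
k_off: 15.7       # sensor backward rate constant, ms^-1
area_convention: sphere
buffers:
  - name: EFB     # endogenous fixed buffer
    D: 0          # um^2/ms (immobile)
    k_on: 100     # mM^-1 ms^-1
    c: 4          # mM  -> binding rate k_01 = 400 ms^-1
    k_off: 10     # ms^-1
  - name: ATP
    D: 0.2
    k_on: 100
    c: 0.2        # -> k_02 = 20 ms^-1
    k_off: 10
  - name: EGTA
    D: 0.22
    k_on: 10.5
    c: 10         # -> k_03 = 105 ms^-1
    k_off: 0.000735
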