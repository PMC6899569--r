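# Synthetic Raman dataset: male wild-type-like vs knockout-like groups.
# Truth folds (ko vs wt): ACP +23.6, OCP -1.17, CAP +1.24;
# amide I chosen so the mineral/matrix fold is -1.33.
wavenumber: {from: 600, to: 1750, step: 1}
noise_sd: 0.03
spike_count: 1
spike_amplitude: 2.0
n_spectra: 50
area_cv: 0.06
baseline: [5.0, 1.5, -0.8, 0.4]
seed: 30101
groups:
  wt:
    bands:
      - {name: ACP,       center: 950.0,  area: 6.0,  width: 5,  eta: 0.3}
      - {name: OCP,       center: 955.0,  area: 12.0, width: 5,  eta: 0.3}
      - {name: CAP,       center: 961.0,  area: 20.0, width: 5,  eta: 0.3}
      - {name: phe,       center: 1004.0, area: 30.0, width: 7,  eta: 0.3}
      - {name: amide_III, center: 1275.0, area: 35.0, width: 22, eta: 0.4}
      - {name: CH2,       center: 1450.0, area: 40.0, width: 14, eta: 0.4}
      - {name: amide_I,   center: 1660.0, area: 60.0, width: 26, eta: 0.4}
  ko:
    bands:
      - {name: ACP,       center: 950.0,  area: 141.6, width: 5,  eta: 0.3}  # 6.0 x 23.6
      - {name: OCP,       center: 955.0,  area: 10.26, width: 5,  eta: 0.3}  # 12 / 1.17
      - {name: CAP,       center: 961.0,  area: 24.8,  width: 5,  eta: 0.3}  # 20 x 1.24
      - {name: phe,       center: 1004.0, area: 30.0,  width: 7,  eta: 0.3}
      - {name: amide_III, center: 1275.0, area: 35.0,  width: 22, eta: 0.4}
      - {name: CH2,       center: 1450.0, area: 40.0,  width: 14, eta: 0.4}
      - {name: amide_I,   center: 1660.0, area: 370.99, width: 26, eta: 0.4} # 176.66 / (0.633333/1.33)
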