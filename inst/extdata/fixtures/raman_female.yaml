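# Synthetic Raman dataset: female wild-type-like vs knockout-like groups.
# Truth folds (ko vs wt): ACP +1.77, OCP +1.21, CAP +10.5;
# amide I chosen so the mineral/matrix fold is +11.9.
# Envelope: wt 25.0, ko 82.3 (fold 3.292); amide I fold 3.292/11.9.
wavenumber: {from: 600, to: 1750, step: 1}
noise_sd: 0.03
spike_count: 1
spike_amplitude: 2.0
n_spectra: 50
area_cv: 0.06
baseline: [5.0, 1.5, -0.8, 0.4]
seed: 30202
groups:
  wt:
    bands:
      - {name: ACP,       center: 950.0,  area: 10.0, width: 5,  eta: 0.3}
      - {name: OCP,       center: 955.0,  area: 10.0, width: 5,  eta: 0.3}
      - {name: CAP,       center: 961.0,  area: 5.0,  width: 5,  eta: 0.3}
      - {name: phe,       center: 1004.0, area: 30.0, width: 7,  eta: 0.3}
      - {name: amide_III, center: 1275.0, area: 35.0, width: 22, eta: 0.4}
      - {name: CH2,       center: 1450.0, area: 40.0, width: 14, eta: 0.4}
      - {name: amide_I,   center: 1660.0, area: 60.0, width: 26, eta: 0.4}
  ko:
    bands:
      - {name: ACP,       center: 950.0,  area: 17.7,  width: 5,  eta: 0.3}  # 10 x 1.77
      - {name: OCP,       center: 955.0,  area: 12.1,  width: 5,  eta: 0.3}  # 10 x 1.21
      - {name: CAP,       center: 961.0,  area: 52.5,  width: 5,  eta: 0.3}  # 5 x 10.5
      - {name: phe,       center: 1004.0, area: 30.0,  width: 7,  eta: 0.3}
      - {name: amide_III, center: 1275.0, area: 35.0,  width: 22, eta: 0.4}
      - {name: CH2,       center: 1450.0, area: 40.0,  width: 14, eta: 0.4}
      - {name: amide_I,   center: 1660.0, area: 16.598, width: 26, eta: 0.4} # 60 x 3.292/11.9
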