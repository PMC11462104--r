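# Synthetic 10-state CVD demo scenario.
# Jump structure follows the packaged jump-frequency fixture; exit rates
# (1/mean hold days) are INVENTED for demonstration - no published holding-time
# parameters exist, so this scenario is illustrative only and is never used as
# ground truth in tests.
states:
  - MI
  - Stroke
  - Death
  - CHF
  - CHMI
  - CHST
  - Angina
  - CHANMI
  - ANMI
  - CHAN
absorbing:
  - Death
rates:
  - {from: MI, to: Stroke, per_day: 0.00003876}
  - {from: MI, to: Death, per_day: 0.00170543}
  - {from: MI, to: CHF, per_day: 0.00120155}
  - {from: MI, to: CHST, per_day: 0.00007752}
  - {from: MI, to: Angina, per_day: 0.00027132}
  - {from: MI, to: CHANMI, per_day: 0.00003876}
  - {from: Stroke, to: MI, per_day: 0.00030534}
  - {from: Stroke, to: Death, per_day: 0.00225954}
  - {from: Stroke, to: CHF, per_day: 0.00054962}
  - {from: Stroke, to: CHMI, per_day: 0.00006107}
  - {from: Stroke, to: CHST, per_day: 0.00027481}
  - {from: Stroke, to: Angina, per_day: 0.00009160}
  - {from: Stroke, to: CHANMI, per_day: 0.00018321}
  - {from: Stroke, to: ANMI, per_day: 0.00021374}
  - {from: Stroke, to: CHAN, per_day: 0.00006107}
  - {from: CHF, to: MI, per_day: 0.00018717}
  - {from: CHF, to: Stroke, per_day: 0.00033422}
  - {from: CHF, to: Death, per_day: 0.00135027}
  - {from: CHF, to: CHMI, per_day: 0.00004011}
  - {from: CHF, to: Angina, per_day: 0.00014706}
  - {from: CHF, to: CHANMI, per_day: 0.00017380}
  - {from: CHF, to: ANMI, per_day: 0.00012032}
  - {from: CHF, to: CHAN, per_day: 0.00014706}
  - {from: CHMI, to: Stroke, per_day: 0.00015873}
  - {from: CHMI, to: Death, per_day: 0.00126984}
  - {from: CHMI, to: CHF, per_day: 0.00095238}
  - {from: CHMI, to: Angina, per_day: 0.00031746}
  - {from: CHMI, to: CHAN, per_day: 0.00015873}
  - {from: CHST, to: MI, per_day: 0.00035714}
  - {from: CHST, to: Stroke, per_day: 0.00214286}
  - {from: CHST, to: Death, per_day: 0.00107143}
  - {from: CHST, to: CHF, per_day: 0.00142857}
  - {from: Angina, to: MI, per_day: 0.00019802}
  - {from: Angina, to: Stroke, per_day: 0.00024202}
  - {from: Angina, to: Death, per_day: 0.00026403}
  - {from: Angina, to: CHF, per_day: 0.00085809}
  - {from: Angina, to: CHMI, per_day: 0.00002200}
  - {from: Angina, to: CHST, per_day: 0.00002200}
  - {from: Angina, to: CHANMI, per_day: 0.00015402}
  - {from: Angina, to: ANMI, per_day: 0.00015402}
  - {from: Angina, to: CHAN, per_day: 0.00030803}
  - {from: CHANMI, to: MI, per_day: 0.00032258}
  - {from: CHANMI, to: Stroke, per_day: 0.00018433}
  - {from: CHANMI, to: Death, per_day: 0.00046083}
  - {from: CHANMI, to: CHF, per_day: 0.00087558}
  - {from: CHANMI, to: CHMI, per_day: 0.00004608}
  - {from: CHANMI, to: Angina, per_day: 0.00059908}
  - {from: CHANMI, to: ANMI, per_day: 0.00018433}
  - {from: CHANMI, to: CHAN, per_day: 0.00018433}
  - {from: ANMI, to: MI, per_day: 0.00014706}
  - {from: ANMI, to: Stroke, per_day: 0.00019608}
  - {from: ANMI, to: Death, per_day: 0.00019608}
  - {from: ANMI, to: CHF, per_day: 0.00073529}
  - {from: ANMI, to: Angina, per_day: 0.00078431}
  - {from: ANMI, to: CHANMI, per_day: 0.00029412}
  - {from: ANMI, to: CHAN, per_day: 0.00014706}
  - {from: CHAN, to: MI, per_day: 0.00005682}
  - {from: CHAN, to: Stroke, per_day: 0.00011364}
  - {from: CHAN, to: Death, per_day: 0.00034091}
  - {from: CHAN, to: CHF, per_day: 0.00107955}
  - {from: CHAN, to: CHMI, per_day: 0.00011364}
  - {from: CHAN, to: Angina, per_day: 0.00045455}
  - {from: CHAN, to: CHANMI, per_day: 0.00028409}
  - {from: CHAN, to: ANMI, per_day: 0.00005682}
initial_distribution:
  MI: 0.135
  Stroke: 0.257
  CHF: 0.442
  Angina: 0.166
n_patients: 500
max_followup_days: 5800
seed: 20260928
decompose_composites: true
duplicate_rate: 0.15
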