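# Example generator configuration for readTruthConfig(): a small synthetic
# study with Gaussian-layer distance and a lowered resting detection rate.
nFish: 6
nDays: 10
lambdaActive: 4
lambdaRest: 0.1
traits:
  awakening:
    Vind: 900
    Ve: 1600
  rest_onset:
    Vind: 16
    Ve: 36
ou:
  beta: 0.2
  stationarySd: 15
  obsSd: 5
config:
  distanceMode: gaussian
  startDate: "2012-06-01"
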