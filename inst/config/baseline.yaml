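# Base-case run configuration: five tax scenarios, market calibrated from
# the published 10%-ad-valorem scenario, synthetic adult cohort, Monte Carlo
# models 1 & 2, one-way elasticity sensitivity analysis.
seed: 42
outputs: ssbtax-out
elasticity: -1.14
scenarios:
  - id: s1
    tax_type: ad_valorem
    rate: 0.10
    avg_price_increase: 0.05
  - id: s2
    tax_type: specific_volume
    rate: 3500        # VND per litre
    avg_price_increase: 0.11
  - id: s3
    tax_type: specific_sugar
    rate: 60          # VND per gram of sugar contained, per litre
    avg_price_increase: 0.19
  - id: s4
    tax_type: specific_volume
    rate: 7000
    avg_price_increase: 0.20
  - id: s5
    tax_type: ad_valorem
    rate: 0.40
    avg_price_increase: 0.20
market:
  decrease_s1: 171.3          # million litres/year
  price_increase_s1: 0.05
  per_capita_decrease_s1: 2.6 # litres/person/year
  sugar_decrease_s1: 0.8      # g/person/day
cohort:
  n: 3856
energy_weight: {}
diabetes: {}
mc:
  enabled: true
  iterations: 10000
  models: [model1, model2]
sa:
  elasticities: [-1.14, -1.0, -0.8]
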