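# Demo pipeline configuration: a small synthetic world that runs end-to-end
# in well under a minute. The full-scale world (51 geographies, baseline
# from 2010) uses the synthetic_config defaults instead.
seed: 20200525
simulate:
  n_geographies: 10
  baseline_start: "2019-06-01"
  event_date: "2020-05-25"
  post_end: "2020-07-05"
model:
  orders: [1, 0, 0]
  level: 0.95
  B: 500
geo:
  contrast_k: 3
  comparison: all
  icc_transform: rank
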