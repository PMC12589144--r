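# HScore total -> published probability-of-sHLH band (%).
# Only the (score, band) pairs actually published for this cohort anchor the
# table; interval boundaries between adjacent anchors are interpolated at
# midpoints and flagged accordingly. Scores below the lowest anchor (174)
# fall back to the lowest band, scores above 337 (the maximum attainable
# total) to the highest.
bands:
  - {lower: 0,   upper: 179, label: "54",  interpolated_upper: true}
  - {lower: 180, upper: 187, label: "70",  interpolated_upper: true}
  - {lower: 188, upper: 198, label: "80",  interpolated_upper: true}
  - {lower: 199, upper: 216, label: "88",  interpolated_upper: true}
  - {lower: 217, upper: 234, label: "96",  interpolated_upper: true}
  - {lower: 235, upper: 254, label: "99",  interpolated_upper: true}
  - {lower: 255, upper: 337, label: ">99", interpolated_upper: false}
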