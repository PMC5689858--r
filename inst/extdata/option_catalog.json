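[
  {
    "option": 1,
    "group": "large",
    "R_min": 22.6,
    "R_max": 25,
    "M_min": 2,
    "M_max": 20,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 177.8,
    "R_L": 22.6,
    "rof_R": 25,
    "rof_M": 10
  },
  {
    "option": 2,
    "group": "large",
    "R_min": 20.1,
    "R_max": 22.5,
    "M_min": 2,
    "M_max": 20,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 176.8,
    "R_L": 20.1,
    "rof_R": 22.5,
    "rof_M": 10
  },
  {
    "option": 3,
    "group": "large",
    "R_min": 18.4,
    "R_max": 20.8,
    "M_min": 2,
    "M_max": 20,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 176,
    "R_L": 18.4,
    "rof_R": 20.8,
    "rof_M": 10
  },
  {
    "option": 4,
    "group": "large",
    "R_min": 16.3,
    "R_max": 18.7,
    "M_min": 2,
    "M_max": 18.7,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 175.1,
    "R_L": 16.3,
    "rof_R": 18.7,
    "rof_M": 10
  },
  {
    "option": 5,
    "group": "large",
    "R_min": 14.3,
    "R_max": 16.7,
    "M_min": 2,
    "M_max": 16.7,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 174.3,
    "R_L": 14.3,
    "rof_R": 16.7,
    "rof_M": 10
  },
  {
    "option": 6,
    "group": "large",
    "R_min": 12.4,
    "R_max": 14.8,
    "M_min": 2,
    "M_max": 14.8,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 173.5,
    "R_L": 12.4,
    "rof_R": 14.8,
    "rof_M": 10
  },
  {
    "option": 7,
    "group": "large",
    "R_min": 10.7,
    "R_max": 13.1,
    "M_min": 2,
    "M_max": 13.1,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 172.8,
    "R_L": 10.7,
    "rof_R": 13.1,
    "rof_M": 10
  },
  {
    "option": 8,
    "group": "large",
    "R_min": 9,
    "R_max": 11.4,
    "M_min": 2,
    "M_max": 11.4,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 172,
    "R_L": 9,
    "rof_R": 11.4,
    "rof_M": 10
  },
  {
    "option": 9,
    "group": "large",
    "R_min": 7.5,
    "R_max": 9.9,
    "M_min": 2,
    "M_max": 9.9,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 171.9,
    "R_L": 7.5,
    "rof_R": 9.9,
    "rof_M": 8
  },
  {
    "option": 10,
    "group": "large",
    "R_min": 6.1,
    "R_max": 8.5,
    "M_min": 2,
    "M_max": 8.5,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 171.9,
    "R_L": 6.1,
    "rof_R": 8.5,
    "rof_M": 6
  },
  {
    "option": 11,
    "group": "large",
    "R_min": 5,
    "R_max": 7.2,
    "M_min": 2,
    "M_max": 7.2,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 171.9,
    "R_L": 5,
    "rof_R": 7.2,
    "rof_M": 6
  },
  {
    "option": 12,
    "group": "large",
    "R_min": 5,
    "R_max": 6,
    "M_min": 2,
    "M_max": 6,
    "applicator": "large",
    "ref_field": "20x20",
    "ESAD": 171.9,
    "R_L": 5,
    "rof_R": 6,
    "rof_M": 4
  },
  {
    "option": 13,
    "group": "deep",
    "R_min": 29.6,
    "R_max": 32,
    "M_min": 2,
    "M_max": 10,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 180.8,
    "R_L": 29.6,
    "rof_R": 32,
    "rof_M": 10
  },
  {
    "option": 14,
    "group": "deep",
    "R_min": 27.1,
    "R_max": 29.5,
    "M_min": 2,
    "M_max": 10,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 179.7,
    "R_L": 27.1,
    "rof_R": 29.5,
    "rof_M": 10
  },
  {
    "option": 15,
    "group": "deep",
    "R_min": 24.6,
    "R_max": 27,
    "M_min": 2,
    "M_max": 10,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 178.7,
    "R_L": 24.6,
    "rof_R": 27,
    "rof_M": 10
  },
  {
    "option": 16,
    "group": "deep",
    "R_min": 22.1,
    "R_max": 24.5,
    "M_min": 2,
    "M_max": 10,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 177.6,
    "R_L": 22.1,
    "rof_R": 24.5,
    "rof_M": 10
  },
  {
    "option": 17,
    "group": "deep",
    "R_min": 20.1,
    "R_max": 22,
    "M_min": 2,
    "M_max": 10,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 176.5,
    "R_L": 20.1,
    "rof_R": 22,
    "rof_M": 10
  },
  {
    "option": 18,
    "group": "small",
    "R_min": 17.6,
    "R_max": 20,
    "M_min": 2,
    "M_max": 20,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 175.7,
    "R_L": 17.6,
    "rof_R": 20,
    "rof_M": 10
  },
  {
    "option": 19,
    "group": "small",
    "R_min": 15.3,
    "R_max": 17.7,
    "M_min": 2,
    "M_max": 17.7,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 174.7,
    "R_L": 15.3,
    "rof_R": 17.7,
    "rof_M": 10
  },
  {
    "option": 20,
    "group": "small",
    "R_min": 12.6,
    "R_max": 15,
    "M_min": 2,
    "M_max": 15,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 173.6,
    "R_L": 12.6,
    "rof_R": 15,
    "rof_M": 10
  },
  {
    "option": 21,
    "group": "small",
    "R_min": 10.8,
    "R_max": 13.2,
    "M_min": 2,
    "M_max": 13.2,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 172.8,
    "R_L": 10.8,
    "rof_R": 13.2,
    "rof_M": 10
  },
  {
    "option": 22,
    "group": "small",
    "R_min": 8.7,
    "R_max": 11.1,
    "M_min": 2,
    "M_max": 11.1,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 171.9,
    "R_L": 8.7,
    "rof_R": 11.1,
    "rof_M": 10
  },
  {
    "option": 23,
    "group": "small",
    "R_min": 6.6,
    "R_max": 9,
    "M_min": 2,
    "M_max": 9,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 171.9,
    "R_L": 6.6,
    "rof_R": 9,
    "rof_M": 8
  },
  {
    "option": 24,
    "group": "small",
    "R_min": 5,
    "R_max": 6.9,
    "M_min": 2,
    "M_max": 6.9,
    "applicator": "small",
    "ref_field": "10x10",
    "ESAD": 171.9,
    "R_L": 5,
    "rof_R": 6.9,
    "rof_M": 6
  }
]
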