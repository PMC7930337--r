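{
  "schema_version": 1,
  "values": {
    "bias_AS": -0.331333474356013,
    "bias_DA": 0.0860218909709047,
    "bias_DB": -0.881074906195521,
    "bias_DD": 0.686195323646449,
    "bias_VD": 0.315894341328561,
    "bias_VA": -0.898640774452624,
    "bias_VB": -0.309518008537998,
    "tau_AS": -0.703520072986443,
    "tau_DA": -0.729688045353817,
    "tau_DB": -0.726095223804914,
    "tau_DD": -0.901473931502105,
    "tau_VD": -0.843312130389059,
    "tau_VA": -0.230382677200543,
    "tau_VB": -0.984556713210091,
    "wself_AS": -0.14362504218461,
    "wself_DA": 0.642719064573449,
    "wself_DB": 0.729846644194718,
    "wself_DD": 0.0401378278597708,
    "wself_VD": 0.2248760247208,
    "wself_VA": -0.251387050381038,
    "wself_VB": -0.274433753757135,
    "nmj_AS": -0.940665276591423,
    "nmj_DA": 0.748628682677428,
    "nmj_DB": 0.0558865320877653,
    "nmj_DD": 0.0203613105522555,
    "nmj_VD": -0.857206892544885,
    "nmj_VA": 0.930707077464769,
    "nmj_VB": -0.914263607946172,
    "AS_to_DA": -0.979225433341445,
    "AS_to_VD": -0.991672727945816,
    "DA_to_DB": 0.986636548657373,
    "DB_to_AS": 0.945448840835617,
    "VD_to_VA": -0.299264409216109,
    "VD_to_VB": 0.945304956598083,
    "DA_to_DD": -0.574293578287559,
    "VB_to_DD": -0.927728007565838,
    "VA_to_DD": -0.613297463465577,
    "g_VD_DD": 0.266040583030645,
    "DB_to_DDp1": -0.0191785410108037,
    "VAp1_to_DD": 0.179380927536414,
    "g_DA_ASp1": -0.589401040509575,
    "g_VB_DBp1": -0.886738161476252,
    "g_AS_VAp1": -0.631625350218128,
    "gain_F": 0.963562928327863
  }
}
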