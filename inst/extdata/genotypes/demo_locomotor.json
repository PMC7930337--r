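{
  "schema_version": 1,
  "values": {
    "bias_AS": -0.378820541010205,
    "bias_DA": -0.0742428826239464,
    "bias_DB": -0.749287954871373,
    "bias_DD": 0.488473377551014,
    "bias_VD": 0.535260863329803,
    "bias_VA": -0.779332275183627,
    "bias_VB": -0.328037516634315,
    "tau_AS": -0.807822572598619,
    "tau_DA": -0.558363723599595,
    "tau_DB": -0.778530923217485,
    "tau_DD": -0.835649879311271,
    "tau_VD": -0.907953312016775,
    "tau_VA": -0.353043765014163,
    "tau_VB": -0.881611481189444,
    "wself_AS": 0.00223934640080003,
    "wself_DA": 0.654931288525434,
    "wself_DB": 0.652675285169523,
    "wself_DD": -0.0418204915325958,
    "wself_VD": 0.215011437971857,
    "wself_VA": 0.0504198392912251,
    "wself_VB": -0.36770253179022,
    "nmj_AS": -1,
    "nmj_DA": -1,
    "nmj_DB": 1,
    "nmj_DD": 0.97003596684951,
    "nmj_VD": -1,
    "nmj_VA": -1,
    "nmj_VB": -0.78418768566372,
    "AS_to_DA": -0.820820217780867,
    "AS_to_VD": -0.831093349053203,
    "DA_to_DB": 0.942735070473087,
    "DB_to_AS": 0.977126898910669,
    "VD_to_VA": -0.46408995662773,
    "VD_to_VB": 0.978779660844032,
    "DA_to_DD": -0.624127011219331,
    "VB_to_DD": -0.81286291824448,
    "VA_to_DD": -0.498718900513649,
    "g_VD_DD": 0.177261516808832,
    "DB_to_DDp1": 0.156508543037536,
    "VAp1_to_DD": -0.00485702206863385,
    "g_DA_ASp1": -0.614397095188841,
    "g_VB_DBp1": -0.5927858275812,
    "g_AS_VAp1": -0.910765791342877,
    "gain_F": -1
  }
}
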