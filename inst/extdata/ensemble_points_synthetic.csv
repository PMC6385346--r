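member,sensitivity,sigma_b,dgpp,dgpp_sd
member_01,0.0751823115180122,0.00739736569930928,4.65293335814765,0.3
member_02,0.0633938094116412,0.00665408500530732,5.13465576476068,0.3
member_03,0.0288027502400501,0.00590322127693903,3.07497530083394,0.3
member_04,0.050640922155808,0.00586604799895661,4.49644774210543,0.3
member_05,0.0581945037322805,0.00513820280978348,4.44947463710489,0.3
member_06,0.0562287208906731,0.00699412274585831,3.37381476782337,0.3
member_07,0.0448028379149611,0.00583872408145659,4.40030406918536,0.3
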