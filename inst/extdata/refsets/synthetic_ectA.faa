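>synEctA_1
LCTTYLPQVHQHTRPPYVDDAKIGASLFDIVLTHTTLSTNHISAPSGDVCCTECLIRAGDLVYKSEQDAFCEKLCAYMVAGEYTCCGDAKGSRSFRTFERRDDAIQNLGVTRFTVEQKNMLKGDHNENRFLTNQVKALRKDQIVNASFGPAQPNLGEEGAST
>synEctA_2
GHWTALALVELFTRPMYVDDAPLVAPLFLIVLTHTTLSTNLQPAPLGWVCDTMNLIQAWDLDYKSEDDAFCEKLPAIQVAGNYPCSGSEFGSSSFLSFWIQVGAIQALGVIRKTVEQKWMLKSDTPEARHLTAQFWALRKIKIVNASFAPAQPNLRIEGASP
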