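>synLuxR_1
GSDMIIEDPKMCTNVETCRPGVTLMATDWIQKALFHISRQYPILNGDQRDILDYAPFEPPTIVMQLFFDDNWQNVGSDEADPAGAEAFKEEQGSFAAFYVTSQIHSDSSTIHQWNDAANLEESRELHFHSYTKADFIRKDESSEIHRSDSQPKHYVVSPAKVAIQAEKTLIRSFRTKVLPTSPRDDRPSLDLQHEARNATMDRSGENAHAPYSLQNAEHRPLLPNVIADTASDFFFWWKY
>synLuxR_2
GGDMHLEDQKMCKNCETLRPGMTLFAPKWRTKALFCASRQEKILYAQQRDINDNADFEPFTTLRQLFFDNNWQNVNSDKIVYAGYEAAKKLIGSFAAFYVTSLIMSELSTVRQHQDALPLEPYNELAFMSSLKADMIPNNESKSPHRVDSERKYGVENLAKVHPDAESTIIRSFRTKVLPTNPRDDRPRLDATHNARNATMNRIGFYAHAPYYLKKAENESPGDNVIADLDYPFFEMWSP
>synLuxR_3
SRDMKIEDLKMCKNPEMLRPSAVLFATYWRQKALFMIERAEKISYGQQRDILDNGDFNPPTPLRSLFFRVNWHNVQSDEAVNAGEEADEKEISSFAKFYCTSNIVSETSTKMQWQDAANLIEYNELPFISGTKAGFIPSHESKEGHWSDSQRRTGVQSLAKVLEMKDKTVIHSDRTKKLPTMDRDDDQSWYAQHEWRNATKRRNGLWAHAPATSQNAIHEDLPPNVIADQDSDFAESWSP
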