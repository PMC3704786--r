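>synArdo_1
VFTQEAFRLGSPQLKSIRGFVILPGKMGSESFASPNLISCNRVAAFTAKIPHMRLPSDWCIHLPIGGENLLAPMKLTSHCLMHMLFAIDVKSTKKGLDRTNVLLDLPNAKKQFRWLDIAIVKGDEVLVQLTLDEDMNDQPRMMQHKSDFAWLLSALDVPLGIDRYDSPGNFQRKNRGIAQVRYRPPPAVANYQDNSPRTHGWYVEADNVIYWASKHSVKD
>synArdo_2
VMTKEAHRLGEPKLKSGRGFEILPGVMGSESFGSPNEISHNRVVAQIAKQPSMRIPSDNCIHLPSGGENSQFCMKLTSVCCDHWLFYIDVKSTKWGLDKTNILLDVPNAKKPNLSLAFAIYKGATVLVTETRAEDTEDQPDMQCQASDFAWLLDALMGPLDIDCYRSPWNHEMKLQNIAQVTYRPPPAVANVIDPSERQGNDINEADNVKYVASKYSVKQ
>synArdo_3
LECQEAERLMIPQLKSGRGFVKLPGRMGSESLASPNEISILRYVAQQAKRPSMPFKSDWCMHLPIGGENLQVPMKLTSVCLRHVLFRIDVHSTIFGLDRTNCQLDAPNAKRQFRSLYFAIVKGAEVLVTLHLALDCELQPRPGQQFSDFAWLLTGLDVPLGIDRRDSPGNQNMKLHIIAHVGYDPPPAVANVQDPSPRVGIWINEADNVKYVPVHCSVKQ
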