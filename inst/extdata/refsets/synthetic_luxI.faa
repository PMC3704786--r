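>synLuxI_1
GFLNVVFCSKETRNYQICIGMVYRKLLFKSLLLWWTAYCYRPSESHLNYDSDWSCQPQSQHRGSALSKADLQQQLPHLPIVQHNAHDNECVQIIFVTGKAFTRVEMELFTSDEDDYDPCVKLAHKIRSAYVKGFTEMCNGTSFVYKLECLSPPKNGNVQIAGDSMFDNVKDQQLHWLLFVLGMGSRLLVRYYLFDFKNLF
>synLuxI_2
LFLNVLFCSKEHYKSMNGIGAVYRKLEFKSPLLWATATSYRPSRSHPTMDSDWSMQALSKLWGLAFVKADQRQQGPYWPVVKGNAHDTECVQIIFVTGKHFTRVWNIHTTSDEVMIDFCKKLAHGIRSANVKPNAELCNGTRQVYKLECLSPPRLGPVAIYQDSPFENVVCSQTWWLLFPDGEGSRPLVRYYLVDDKMLS
>synLuxI_3
VFPNVGPDSKEHYNDEICIVANYRKLCFKEELQWATAYSYRPSESYLQMHSDWSAQFQPKLRGSASVKTDQPYQLPDEMEVFGNAHDTHCGQIIFVTDKAFTRNENEYTTRDEVIIDQCVKLADGSRFAYVRPNAEFCNGNATGYKLRKWNMVPNGRVQIAGDLEFDNGREQQFHSFLFSKGEGSRILLRYYLVDIKQYT
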